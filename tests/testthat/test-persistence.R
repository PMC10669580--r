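test_that("grayscale conversion uses rounded Rec. 601 luminance", {
  expect_equal(to_grayscale(array(255, dim = c(1, 1, 3)))[1, 1], 255)
  expect_equal(to_grayscale(array(0, dim = c(1, 1, 3)))[1, 1], 0)
  expect_equal(to_grayscale(array(c(100, 200, 50), dim = c(1, 1, 3)))[1, 1],
               153)  # round(29.9 + 117.4 + 5.7)
})

test_that("H0 bars match hand-computed filtrations", {
  # constant image: single essential component
  p <- h0_persistence(matrix(7, 4, 5))
  expect_equal(nrow(p$bars), 1)
  expect_equal(p$bars$birth, 7)
  expect_equal(p$bars$death, Inf)

  # 1x5 row [5,1,5,0,5]: the value-1 basin merges into the value-0 one at 5
  p <- h0_persistence(matrix(c(5, 1, 5, 0, 5), nrow = 1))
  expect_equal(p$bars$birth, c(0, 1))
  expect_equal(p$bars$death, c(Inf, 5))

  # two value-0 squares on a 255 background, with value-200 speckles
  g <- matrix(255, 20, 20)
  g[3:6, 3:6] <- 0
  g[14:17, 14:17] <- 0
  g[3, 15] <- 200; g[17, 4] <- 200
  p <- h0_persistence(g)
  expect_equal(p$bars$birth[1], 0)
  expect_true(is.infinite(p$bars$death[1]))
  fin <- p$bars[is.finite(p$bars$death), ]
  expect_equal(fin$birth[fin$lifespan == 255], 0)
  expect_equal(sum(fin$lifespan == 55), 2)  # both speckles
})

test_that("exactly one essential bar exists on random images", {
  set.seed(5)
  for (i in 1:20) {
    g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    p <- h0_persistence(g)
    expect_equal(sum(!is.finite(p$bars$death)), 1)
    expect_true(all(p$bars$lifespan >= 0))
    expect_true(all(p$bars$death >= p$bars$birth))
  }
})

test_that("union-find bars equal the flood-fill sweep oracle", {
  set.seed(17)
  for (i in 1:30) {
    g <- matrix(sample(seq(0, 255, length.out = 6), 144, replace = TRUE),
                12, 12)
    p <- h0_persistence(g)
    oracle <- brute_bars(g)
    expect_equal(pkg_finite_bars(p), oracle$finite)
    expect_equal(p$bars$birth[!is.finite(p$bars$death)],
                 oracle$essential_birth)
  }
})

test_that("a brighter speckle on the background only adds bars", {
  set.seed(31)
  for (i in 1:10) {
    # dark blobs on a constant bright plateau
    g <- matrix(255, 14, 14)
    for (b in 1:3) {
      r <- sample(2:10, 1); c <- sample(2:10, 1)
      g[r:(r + sample(1:3, 1)), c:(c + sample(1:3, 1))] <-
        sample(0:120, 1)
    }
    p0 <- h0_persistence(g)
    # place the speckle on a plateau pixel whose 4-neighbors are untouched
    cand <- which(g == 255, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < 14 &
                 cand[, 2] > 1 & cand[, 2] < 14, , drop = FALSE]
    ok <- apply(cand, 1, function(rc)
      g[rc[1] - 1, rc[2]] == 255 && g[rc[1] + 1, rc[2]] == 255 &&
      g[rc[1], rc[2] - 1] == 255 && g[rc[1], rc[2] + 1] == 255)
    rc <- cand[which(ok)[1], ]
    g2 <- g; g2[rc[1], rc[2]] <- 220  # brighter than every structure
    p1 <- h0_persistence(g2)
    b0 <- pkg_finite_bars(p0); b1 <- pkg_finite_bars(p1)
    # every original finite bar persists; exactly one bar [220, 255) appears
    for (j in seq_len(nrow(b0))) {
      hit <- which(b1[, 1] == b0[j, 1] & b1[, 2] == b0[j, 2])
      expect_gte(length(hit), 1)
      b1 <- b1[-hit[1], , drop = FALSE]
    }
    expect_equal(b1, matrix(c(220, 255), 1))
    expect_equal(p1$bars$birth[!is.finite(p1$bars$death)],
                 p0$bars$birth[!is.finite(p0$bars$death)])
  }
})

test_that("lifespan threshold is the largest-gap midpoint", {
  mk <- function(ls) data.frame(birth = 0, death = 0, lifespan = ls,
                                birth_pixel = 1)
  expect_equal(as.numeric(lifespan_threshold(mk(c(255, 255)))), 0)
  t1 <- lifespan_threshold(mk(c(255, 250, 6, 5, 2)))
  expect_equal(as.numeric(t1), 128)
  expect_false(attr(t1, "ambiguous"))
  t2 <- lifespan_threshold(mk(c(255, 140, 130, 2)))
  expect_equal(as.numeric(t2), 66)
  expect_true(attr(t2, "ambiguous"))  # 2nd-3rd gap under 10% of the 2nd
})

test_that("contrast enhancement is idempotent on separated input", {
  g <- matrix(255, 16, 16)
  g[5:10, 5:10] <- 0
  p <- h0_persistence(g)
  out <- enhance_contrast(g, p, lifespan_threshold(p))
  expect_equal(out, g)

  cg <- matrix(42, 8, 8)
  pc <- h0_persistence(cg)
  expect_equal(enhance_contrast(cg, pc, lifespan_threshold(pc)), cg)
})

test_that("contrast enhancement erases speckles and keeps the blob", {
  g <- matrix(255, 24, 24)
  g[8:16, 8:16] <- 60
  speckles <- rbind(c(2, 20), c(20, 2), c(3, 3), c(22, 22))
  g[speckles] <- 230
  p <- h0_persistence(g)
  thr <- lifespan_threshold(p)
  out <- enhance_contrast(g, p, thr)
  expect_true(all(out[speckles] == 255))
  expect_true(all(out[8:16, 8:16] <= 60))
  # re-running persistence on the output: speckle bars are gone, and the
  # number of above-threshold components is unchanged
  p2 <- h0_persistence(out)
  expect_equal(sum(pmin(p2$bars$lifespan, 255) > thr),
               sum(pmin(p$bars$lifespan, 255) > thr))
  expect_false(any(pkg_finite_bars(p2)[, 1] == 230))
})
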