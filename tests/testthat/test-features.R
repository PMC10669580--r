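test_that("area and perimeter match hand-traced chains", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  ap <- area_perimeter(sq)
  expect_equal(ap$A, 100)
  expect_equal(ap$P, 36)  # 4 sides of 9 unit steps through pixel centers
  expect_false(ap$degenerate)

  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  ap1 <- area_perimeter(one)
  expect_equal(ap1$A, 1)
  expect_equal(ap1$P, 0)
  expect_true(ap1$degenerate)

  d <- disk_mask(128, 50)
  apd <- area_perimeter(d)
  expect_lt(abs(apd$A - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(apd$P - 2 * pi * 50) / (2 * pi * 50), 0.03)
})

test_that("circularity and compactness follow their closed forms", {
  expect_equal(border_irregularity(A = pi * 10^2, P = 2 * pi * 10), 1)
  expect_equal(border_irregularity(A = 100, P = 40), pi / 4)
  expect_equal(compactness(A = pi * 10^2, P = 2 * pi * 10), 1)
  expect_equal(compactness(A = 100, P = 40), 4 / pi)
  # digital disk: circularity within 2% of the circle optimum
  d <- disk_mask(128, 50)
  expect_lt(abs(border_irregularity(d) - 1), 0.02)
})

test_that("circularity times compactness is exactly 1 on any mask", {
  for (seed in 1:6) {
    les <- make_lesion(lesion_spec(base_radius = 30,
                                   harmonic_amplitudes = c(0.1, 0.1),
                                   seed = seed))
    ap <- area_perimeter(les$mask)
    expect_equal(border_irregularity(ap$A, ap$P) * compactness(ap$A, ap$P),
                 1)
  }
})

test_that("NEF hits its filament and square limits", {
  line <- matrix(0L, 3, 40); line[2, ] <- 1L
  expect_equal(as.numeric(nef_shape_asymmetry(line)), 1)
  sq <- matrix(1L, 16, 16)
  expect_equal(as.numeric(nef_shape_asymmetry(sq)), 0)
  tiny <- matrix(0L, 4, 4); tiny[1, 1:3] <- 1L
  expect_true(attr(nef_shape_asymmetry(tiny), "degenerate"))
  # elongation raises NEF at matched area
  d <- disk_mask(101, 30)
  e <- ellipse_mask(151, 60, 15)
  expect_gt(as.numeric(nef_shape_asymmetry(e)),
            as.numeric(nef_shape_asymmetry(d)))
})

test_that("box-counting dimension is right for lines, circles and Koch", {
  line <- matrix(0L, 64, 128); line[32, 10:120] <- 1L
  line_thick <- line; line_thick[33, 10:120] <- 1L  # avoid degenerate bbox
  expect_lt(abs(fractal_dimension(line_thick) - 1), 0.1)

  d <- disk_mask(256, 80)
  expect_lt(abs(fractal_dimension(d) - 1), 0.1)

  koch <- koch_boundary_points(4)
  expect_lt(abs(box_counting_dimension(koch) - log(4) / log(3)), 0.12)
})

test_that("dominant colors recover painted mixtures", {
  img <- flat_rgb(80, 80)
  d <- disk_mask(80, 25)
  px <- which(d > 0)
  n <- length(px)
  paints <- rbind(c(101, 67, 33), c(205, 133, 63), c(113, 128, 147))
  split <- c(rep(1, round(0.5 * n)), rep(2, round(0.3 * n)))
  split <- c(split, rep(3, n - length(split)))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[px] <- paints[split, ch]
    img[, , ch] <- plane
  }
  dc <- dominant_colors(img, d, k = 3, seed = 2)
  got <- dc$centers[order(dc$centers[, 1]), ]
  want <- paints[order(paints[, 1]), ]
  expect_true(all(abs(got - want) <= 2))

  # single color: one centroid equals the paint, all pixels together
  img1 <- paint_mask(flat_rgb(60, 60), disk_mask(60, 18), c(101, 67, 33))
  dc1 <- dominant_colors(img1, disk_mask(60, 18), k = 3, seed = 1)
  expect_true(any(apply(dc1$centers, 1, function(cc)
    all(cc == c(101, 67, 33)))))
  expect_equal(length(unique(dc1$assignment)), 1)
})

test_that("palette assignment is nearest-anchor with palette-order ties", {
  expect_equal(palette_assign(c(255, 255, 255)), "white")
  expect_equal(palette_assign(c(250, 5, 5)), "red")
  # brute-force distance table for the gray midpoint
  pal <- dermoscopy_palette()
  p <- c(128, 128, 128)
  d2 <- apply(pal[, c("r", "g", "b")], 1, function(a) sum((a - p)^2))
  expect_equal(palette_assign(p), pal$name[which.min(d2)])
  expect_equal(palette_assign(p), "blue_gray")
})

test_that("color density reflects construction and sums to 100", {
  img <- paint_mask(flat_rgb(80, 80), disk_mask(80, 25), c(101, 67, 33))
  dens <- color_density(img, disk_mask(80, 25), seed = 1)
  expect_equal(unname(dens["density_dark_brown"]), 100)
  expect_equal(sum(dens), 100)

  # 70/30 two-color paint
  d <- disk_mask(90, 28)
  px <- which(d > 0); n <- length(px)
  img2 <- flat_rgb(90, 90)
  k <- round(0.7 * n)
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[px[1:k]] <- c(101, 67, 33)[ch]
    plane[px[(k + 1):n]] <- c(255, 0, 0)[ch]
    img2[, , ch] <- plane
  }
  dens2 <- color_density(img2, d, seed = 3)
  expect_lt(abs(dens2["density_dark_brown"] - 70), 2)
  expect_lt(abs(dens2["density_red"] - 30), 2)
  expect_equal(sum(dens2), 100, tolerance = 1e-9)
})

test_that("color asymmetry separates symmetric and half-half lesions", {
  # symmetric single-color lesion: near-zero index
  d <- disk_mask(101, 32)
  img <- paint_mask(flat_rgb(101, 101), d, c(101, 67, 33))
  np <- normalize_pose(img, d)
  sec <- eight_sectors(np)
  expect_lte(as.numeric(color_asymmetry(np, sec)), 0.05)

  # halves split across the minor (vertical) axis with disjoint gray values
  e <- ellipse_mask(151, 50, 25)
  img2 <- flat_rgb(151, 151)
  cols <- matrix(rep(seq_len(151), each = 151), 151, 151)
  left <- e > 0 & cols <= 76
  right <- e > 0 & cols > 76
  img2 <- paint_mask(img2, e, c(101, 67, 33), where = left)
  img2 <- paint_mask(img2, e, c(205, 133, 63), where = right)
  np2 <- normalize_pose(img2, e)
  sec2 <- eight_sectors(np2)
  expect_gte(as.numeric(color_asymmetry(np2, sec2)), 1.0)

  # rotating the normalized lesion by 180 degrees swaps opposite sectors
  # and leaves the index unchanged
  D <- nrow(np2$mask)
  np3 <- np2
  np3$image <- np2$image[D:1, D:1, , drop = FALSE]
  np3$mask <- np2$mask[D:1, D:1]
  sec3 <- eight_sectors(np3)
  expect_equal(as.numeric(color_asymmetry(np3, sec3)),
               as.numeric(color_asymmetry(np2, sec2)), tolerance = 1e-6)
})

test_that("color spread follows the population-sd formula", {
  expect_equal(color_sd(rep(100 / 6, 6)), 0)
  expect_equal(color_sd(c(100, 0, 0, 0, 0, 0)), 37.2678, tolerance = 1e-4)
  d <- c(40, 25, 15, 10, 7, 3)
  expect_equal(color_sd(d), color_sd(rev(d)))
})

test_that("the range normalizer maps training extremes to range ends", {
  raw <- data.frame(border_irregularity = c(0.4, 0.7, 1.0),
                    color_sd = c(10, 20, 40))
  nrm <- normalize_features(raw)
  out <- predict(nrm, raw)
  expect_equal(out$border_irregularity, c(0, 2.5, 5))
  expect_equal(out$color_sd, c(0, 100 / 3, 100))
  # clamping of out-of-range test values
  out2 <- predict(nrm, data.frame(border_irregularity = c(0.1, 2),
                                  color_sd = c(-5, 80)))
  expect_equal(out2$border_irregularity, c(0, 5))
  expect_equal(out2$color_sd, c(0, 100))
  # held-out value at the training median of a symmetric sample -> midpoint
  expect_equal(predict(nrm, data.frame(border_irregularity = 0.7,
                                       color_sd = 25))$border_irregularity,
               2.5)
  # determinism: applying a normalizer twice gives identical output
  expect_identical(predict(nrm, raw), predict(nrm, raw))
  # constant feature maps to the midpoint, with a warning
  expect_warning(nc <- normalize_features(
    data.frame(color_sd = c(3, 3), border_irregularity = c(1, 2))))
  expect_equal(predict(nc, data.frame(color_sd = 3,
                                      border_irregularity = 1))$color_sd, 50)
})

test_that("a noiseless single-color disk scores null on every feature", {
  sp <- lesion_spec(base_radius = 32, noise_sd = 0,
                    palette_weights = c(dark_brown = 1))
  les <- make_lesion(sp)
  f <- extract_features(les)
  expect_lt(abs(f$border_irregularity - 1), 0.03)
  expect_lt(f$shape_asymmetry, 0.1)
  expect_lte(f$color_asymmetry, 0.05)
  expect_equal(f$density_dark_brown, 100)
  expect_equal(f$color_sd, color_sd(c(100, 0, 0, 0, 0, 0)))
})

test_that("harmonic sweep moves circularity down and NEF up monotonically", {
  f <- lapply(c(0, 0.1, 0.2, 0.3), function(a2) {
    les <- make_lesion(lesion_spec(base_radius = 35,
                                   harmonic_amplitudes = c(a2), seed = 6))
    extract_features(les)
  })
  circ <- vapply(f, `[[`, numeric(1), "border_irregularity")
  nef <- vapply(f, `[[`, numeric(1), "shape_asymmetry")
  expect_true(all(diff(circ) < 0))
  expect_true(all(diff(nef) > 0))
})

test_that("features are robust to rotating the input by 90 degrees", {
  sp <- lesion_spec(base_radius = 30, harmonic_amplitudes = c(0.15, 0.08),
                    asymmetry_shift = 0.15, noise_sd = 0,
                    palette_weights = c(dark_brown = 0.6, red = 0.4),
                    seed = 21)
  les <- make_lesion(sp)
  rot_img <- aperm(les$image, c(2, 1, 3))[dim(les$image)[2]:1, , ,
                                          drop = FALSE]
  rot_mask <- t(les$mask)[dim(les$mask)[2]:1, ]
  f1 <- extract_features(les$image, les$mask)
  f2 <- extract_features(rot_img, rot_mask)
  for (cl in c("shape_asymmetry", "border_irregularity",
               "fractal_dimension", "compactness", "color_sd")) {
    expect_lt(abs(f1[[cl]] - f2[[cl]]) / max(abs(f1[[cl]]), 1e-9), 0.05)
  }
})

test_that("raw feature invariants hold across random lesions", {
  ds <- make_dataset(15, 15, seed = 8)
  for (li in ds$images) {
    f <- extract_features(li)
    expect_gt(f$border_irregularity, 0)
    expect_lte(f$border_irregularity, 1.1)
    expect_gte(f$compactness, 0.9)
    expect_equal(f$border_irregularity * f$compactness, 1)
    expect_gte(f$fractal_dimension, 0.9)
    expect_lte(f$fractal_dimension, 2.0)
    dens <- unlist(f[grep("^density_", names(f))])
    expect_true(all(dens >= 0))
    expect_equal(sum(dens), 100, tolerance = 1e-6)
  }
})
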