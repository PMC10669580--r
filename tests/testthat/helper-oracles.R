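# Fixtures and independent oracles used across the suite. The oracles
# deliberately avoid the package's own code paths: the persistence oracle
# sweeps threshold levels with EBImage's flood-fill labeling, the radial
# oracle scans mask pixels directly, and the shape fixtures are analytic.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a > 0) + sum(b > 0))

disk_mask <- function(D, r, cx = (D + 1) / 2, cy = (D + 1) / 2) {
  cc <- matrix(rep(seq_len(D), each = D), D, D)
  rr <- matrix(rep(seq_len(D), D), D, D)
  ((cc - cx)^2 + (rr - cy)^2 <= r^2) + 0L
}

ellipse_mask <- function(D, a, b) {
  ctr <- (D + 1) / 2
  cc <- matrix(rep(seq_len(D), each = D), D, D)
  rr <- matrix(rep(seq_len(D), D), D, D)
  (((cc - ctr) / a)^2 + ((rr - ctr) / b)^2 <= 1) + 0L
}

flat_rgb <- function(H, W, rgb = c(224, 172, 138)) {
  array(rep(rgb, each = H * W), dim = c(H, W, 3))
}

# paint palette color `rgb` over mask pixels of a flat background image
paint_mask <- function(img, mask, rgb, where = mask > 0) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[where] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

# Brute-force H0 bars by sweeping every threshold level with 4-connected
# flood-fill labeling (EBImage::bwlabel) and elder-rule bookkeeping: a new
# label containing no previously-alive component opens a bar; a label
# absorbing k >= 1 alive components keeps the eldest and closes the others
# at the current level. Returns the finite bars as a sorted matrix plus the
# essential birth.
brute_bars <- function(gray) {
  levels <- sort(unique(as.vector(gray)))
  alive <- list()  # each: list(rep = pixel index, birth)
  finite <- list()
  for (t in levels) {
    lab <- EBImage::bwlabel((gray <= t) + 0)
    groups <- list()
    for (comp in alive) {
      l <- lab[comp$rep]
      key <- as.character(l)
      groups[[key]] <- c(groups[[key]], list(comp))
    }
    for (l in setdiff(unique(lab[lab > 0]), 0)) {
      key <- as.character(l)
      members <- groups[[key]]
      if (is.null(members)) {
        rep_px <- which(lab == l)[1]
        groups[[key]] <- list(list(rep = rep_px, birth = t))
      } else if (length(members) > 1) {
        births <- vapply(members, `[[`, numeric(1), "birth")
        keep <- which.min(births)
        for (i in seq_along(members))
          if (i != keep)
            finite[[length(finite) + 1]] <- c(members[[i]]$birth, t)
        groups[[key]] <- list(members[[keep]])
      }
    }
    alive <- lapply(groups, `[[`, 1)
  }
  stopifnot(length(alive) == 1)
  fin <- if (length(finite)) do.call(rbind, finite)
         else matrix(numeric(0), ncol = 2)
  fin <- fin[order(fin[, 1], fin[, 2]), , drop = FALSE]
  list(finite = unname(fin), essential_birth = alive[[1]]$birth)
}

# sorted finite-bar matrix from an h0_persistence object, for comparison
pkg_finite_bars <- function(pers) {
  b <- pers$bars[is.finite(pers$bars$death), c("birth", "death")]
  m <- as.matrix(b)
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

# max/min boundary radius of a mask by brute-force radial scan: for each
# angular bin, the largest center distance among foreground pixels
radial_profile <- function(mask, nbins = 72) {
  ctr <- (dim(mask) + 1) / 2
  px <- which(mask > 0, arr.ind = TRUE)
  dy <- px[, 1] - ctr[1]; dx <- px[, 2] - ctr[2]
  th <- (atan2(dy, dx) %% (2 * pi))
  bin <- pmin(floor(th / (2 * pi / nbins)) + 1, nbins)
  r <- sqrt(dx^2 + dy^2)
  vapply(seq_len(nbins), function(b) max(r[bin == b], -Inf), numeric(1))
}

# Koch snowflake boundary pixels (rasterized polyline), for the fractal
# dimension reference D = log 4 / log 3
koch_boundary_points <- function(iterations = 4, side = 243) {
  koch_segment <- function(p1, p2, depth) {
    if (depth == 0) return(rbind(p1))
    a <- p1 + (p2 - p1) / 3
    b <- p1 + 2 * (p2 - p1) / 3
    d <- b - a
    peak <- a + d / 2 + c(-d[2], d[1]) * sqrt(3) / 2
    rbind(koch_segment(p1, a, depth - 1),
          koch_segment(a, peak, depth - 1),
          koch_segment(peak, b, depth - 1),
          koch_segment(b, p2, depth - 1))
  }
  v <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2), c(0, 0))
  pts <- do.call(rbind, lapply(1:3, function(i)
    koch_segment(v[i, ], v[i + 1, ], iterations)))
  # rasterize: dense samples along consecutive vertices
  out <- list()
  n <- nrow(pts)
  for (i in seq_len(n)) {
    p1 <- pts[i, ]; p2 <- pts[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
    out[[i]] <- cbind(p1[1] + ts * (p2[1] - p1[1]),
                      p1[2] + ts * (p2[2] - p1[2]))
  }
  unique(round(do.call(rbind, out)))
}

# small record table emulating the two training sources plus the test one
toy_records <- function(n_b1b = 20, n_b1m = 13, n_b2b = 4, n_b2m = 3,
                        n_b3b = 8, n_b3m = 2) {
  mk <- function(n, label, source, tag)
    if (n > 0) data.frame(id = sprintf("%s_%s_%03d", source, tag, seq_len(n)),
                          label = label, source = source)
    else NULL
  do.call(rbind, list(
    mk(n_b1b, "benign", "DB1", "b"), mk(n_b1m, "malignant", "DB1", "m"),
    mk(n_b2b, "benign", "DB2", "b"), mk(n_b2m, "malignant", "DB2", "m"),
    mk(n_b3b, "benign", "DB3", "b"), mk(n_b3m, "malignant", "DB3", "m")))
}

# separable two-class gaussian feature table for classifier sanity checks
gaussian_features <- function(n_per_class, shift = 3, seed = 1, p = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = as.data.frame(x),
       y = rep(c("benign", "malignant"), each = n_per_class))
}
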