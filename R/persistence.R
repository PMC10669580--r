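#' 0-dimensional persistence of an intensity image
#'
#' Tracks connected components of the sublevel sets of a grayscale image on
#' the 4-connected pixel grid as the intensity threshold grows. Each
#' component is a bar `[birth, death)`; at a merge the component with the
#' earlier birth survives (elder rule). Exactly one bar — the component of
#' the globally earliest pixel — never dies and is reported with `death =
#' Inf` (the essential bar). Under `dark_low` polarity dark structures (a
#' pigmented lesion on lighter skin) are born first and the lesion is
#' normally the essential component; `bright_low` inverts the image before
#' filtering.
#'
#' Zero-lifespan bars (plateau pixels absorbed at their own birth level) are
#' dropped; their pixels are attributed to the absorbing component.
#'
#' @param gray `H x W` matrix of intensities in 0-255 (values are rounded).
#' @param polarity `"dark_low"` (default; filtration on the raw intensities)
#'   or `"bright_low"` (filtration on `255 - intensity`).
#' @return an object of class `h0_persistence`: a list with
#'   \item{bars}{data.frame `birth`, `death` (`Inf` for the essential bar),
#'     `lifespan`, `birth_pixel` (linear index, column-major), sorted by
#'     decreasing lifespan with the essential bar first;}
#'   \item{pixel_bar}{`H x W` matrix mapping each pixel to its bar (row of
#'     `bars`);}
#'   \item{growth}{data.frame `level`, `size`: growth curve of the essential
#'     component, used to locate the background flood;}
#'   \item{polarity, dim}{bookkeeping.}
#' All births/deaths are reported on the filtration scale (inverted scale
#' under `bright_low`).
#' @examples
#' g <- matrix(c(5, 1, 5, 0, 5), nrow = 1)
#' h0_persistence(g)$bars  # bars [0, Inf) and [1, 5)
#' @seealso [lifespan_threshold()], [enhance_contrast()]
#' @export
h0_persistence <- function(gray, polarity = c("dark_low", "bright_low")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(gray), nrow(gray) >= 1, ncol(gray) >= 1)
  v <- round(gray)
  stopifnot(all(v >= 0), all(v <= 255))
  if (polarity == "bright_low") v <- 255 - v

  # C++ core walks pixels row-major; feed the transpose so linear indices
  # returned for birth pixels match R's column-major order on `gray`
  res <- h0_persist_cpp(as.integer(t(v)), nrow(v), ncol(v))

  birth <- res$birth
  death <- res$death
  finite <- !is.na(death)
  lifespan <- ifelse(finite, death - birth, Inf)
  essential <- res$essential + 1L

  # resolve pixels of zero-lifespan bars to the absorbing bar (follow merge
  # links until a bar with positive lifespan, or the essential bar)
  merged <- res$merged_into + 1L
  is_zero <- finite & lifespan == 0
  resolve <- seq_along(birth)
  for (b in which(is_zero)) {
    t <- b
    while (is_zero[t] && !is.na(merged[t])) t <- merged[t]
    resolve[b] <- t
  }
  pixel_bar_raw <- resolve[res$pixel_bar + 1L]

  keep <- which(!finite | lifespan > 0)
  # order: essential first, then decreasing lifespan (stable)
  keep <- keep[order(-ifelse(is.finite(lifespan[keep]), lifespan[keep], Inf),
                     birth[keep])]
  keep <- c(essential, setdiff(keep, essential))

  remap <- integer(length(birth))
  remap[keep] <- seq_along(keep)
  # any pixel still pointing at a dropped bar maps to its resolved target
  pb <- remap[pixel_bar_raw]

  # convert row-major birth pixel index back to column-major
  bp_rm <- res$birth_pixel[keep]
  r0 <- bp_rm %/% ncol(v)
  c0 <- bp_rm %% ncol(v)
  bp_cm <- c0 * nrow(v) + r0 + 1L

  bars <- data.frame(
    birth = birth[keep],
    death = ifelse(is.na(death[keep]), Inf, death[keep]),
    lifespan = lifespan[keep],
    birth_pixel = bp_cm)

  structure(list(
    bars = bars,
    pixel_bar = matrix(pb, nrow(v), ncol(v), byrow = TRUE),
    growth = data.frame(level = res$growth_level, size = res$growth_size),
    polarity = polarity,
    dim = dim(v)), class = "h0_persistence")
}

#' @export
print.h0_persistence <- function(x, ...) {
  cat("H0 persistence (", x$polarity, "), ", nrow(x$bars), " bars on a ",
      x$dim[1], "x", x$dim[2], " image\n", sep = "")
  print(head(x$bars, 10))
  invisible(x)
}

#' Lifespan threshold separating signal components from noise
#'
#' Finds the intensity lifespan below which bars are considered noise: the
#' midpoint of the largest gap between consecutive sorted lifespans, with
#' the essential bar's infinite lifespan finite-ized to the full intensity
#' range (255). With fewer than 3 bars there is nothing to separate and the
#' threshold is 0. An `ambiguous` attribute flags runs where the gap between
#' the 2nd and 3rd longest lifespans is less than 10% of the 2nd — i.e.
#' where "the two dominant components" are not clearly separated from the
#' rest.
#'
#' @param bars an `h0_persistence` object, or its `bars` data.frame.
#' @return numeric threshold with attribute `ambiguous` (logical).
#' @examples
#' b <- data.frame(birth = 0, death = 0,
#'                 lifespan = c(255, 250, 6, 5, 2), birth_pixel = 1)
#' lifespan_threshold(b)  # 128
#' @export
lifespan_threshold <- function(bars) {
  if (inherits(bars, "h0_persistence")) bars <- bars$bars
  ls <- sort(pmin(bars$lifespan, 255), decreasing = TRUE)
  if (length(ls) < 3)
    return(structure(0, ambiguous = FALSE))
  gaps <- ls[-length(ls)] - ls[-1]
  i <- which.max(gaps)
  thr <- (ls[i] + ls[i + 1]) / 2
  structure(thr, ambiguous = (ls[2] - ls[3]) < 0.1 * ls[2])
}

#' Persistence-guided contrast enhancement
#'
#' Destroys image components whose bar lifespan does not exceed the
#' threshold and stretches the contrast between the surviving components and
#' the background. Concretely: pixels of short-lived bars are raised to the
#' bar's death level (the level at which the component merged into a larger
#' structure), erasing speckles; each surviving bar's object — its connected
#' component just before death, and for the essential bar just before the
#' background flood (the largest jump of its growth curve) — is flattened to
#' the bar's birth level; all remaining pixels are set to the image's modal
#' intensity (the level of the essential component at full growth, i.e. the
#' skin background). The number of components with lifespan above the
#' threshold is unchanged.
#'
#' @param gray `H x W` intensity matrix (same one passed to
#'   [h0_persistence()]).
#' @param bars `h0_persistence` object for `gray`.
#' @param threshold lifespan threshold, from [lifespan_threshold()].
#' @return enhanced `H x W` intensity matrix in 0-255, on the original
#'   intensity scale (re-inverted under `bright_low`).
#' @export
enhance_contrast <- function(gray, bars, threshold) {
  stopifnot(inherits(bars, "h0_persistence"))
  v <- round(gray)
  if (bars$polarity == "bright_low") v <- 255 - v
  stopifnot(all(dim(v) == bars$dim))

  bg <- modal_intensity(v)
  out <- matrix(bg, nrow(v), ncol(v))
  b <- bars$bars
  kept <- which(pmin(b$lifespan, 255) > threshold)
  # longest-lived claim pixels first
  kept <- kept[order(-pmin(b$lifespan[kept], 255))]

  # simplification pass: short bars' pixels raised to their death level
  short <- is.finite(b$lifespan) & pmin(b$lifespan, 255) <= threshold
  death_of <- ifelse(short, b$death, -Inf)
  v_simpl <- pmax(v, matrix(death_of[bars$pixel_bar], nrow(v), ncol(v)))

  claimed <- matrix(FALSE, nrow(v), ncol(v))
  ess_level <- essential_object_level(bars)
  for (i in kept) {
    if (is.finite(b$death[i])) {
      level <- b$death[i] - 1
      if (!is.na(ess_level)) level <- min(level, ess_level)
    } else {
      if (is.na(ess_level)) next
      level <- ess_level
    }
    if (level < b$birth[i]) next
    sub <- (v_simpl <= level) & !claimed
    if (!sub[b$birth_pixel[i]]) next
    lab <- EBImage::bwlabel(sub + 0)
    comp <- lab == lab[b$birth_pixel[i]]
    out[comp] <- b$birth[i]
    claimed <- claimed | comp
  }

  out <- pmin(pmax(out, 0), 255)
  if (bars$polarity == "bright_low") out <- 255 - out
  out
}

# Intensity level delimiting the essential component's object (the lesion)
# from the background flood. The per-level growth increments of the
# essential component show a dominant peak where the background floods in;
# the object's cut is the flood onset: the last level below the peak where
# the increment falls under 2% of the peak. Levels at or below the
# essential birth are excluded from the peak search so that a clipped dark
# lesion (mass at level 0) is not mistaken for the flood.
essential_object_level <- function(bars, onset_frac = 0.02) {
  growth <- bars$growth
  if (nrow(growth) < 2) return(NA_integer_)
  birth <- bars$bars$birth[!is.finite(bars$bars$death)][1]
  w <- integer(256)
  w[growth$level + 1L] <- diff(c(0L, growth$size))
  cand <- (birth + 2L):256L  # 1-based slots for levels > birth
  if (length(cand) < 2) return(NA_integer_)
  peak <- cand[which.max(w[cand])]
  below <- cand[cand < peak & w[cand] <= onset_frac * w[peak]]
  if (length(below) == 0) return(as.integer(birth))
  as.integer(max(below) - 1L)  # back to 0-based intensity
}
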