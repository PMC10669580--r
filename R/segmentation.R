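#' @name segmentation-failure
#' @title Segmentation failure condition
#' @description Segmentation raises a condition of class
#' `lesionlab_segmentation_failure` when no lesion can be delineated (no
#' iso-valued contour, empty mask, or a selected component too small to be a
#' lesion). Batch code can test for it with `is_segmentation_failure()` on a
#' `tryCatch`ed result.
NULL

segmentation_failure <- function(msg) {
  stop(structure(class = c("lesionlab_segmentation_failure", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @rdname segmentation-failure
#' @param x object to test.
#' @export
is_segmentation_failure <- function(x)
  inherits(x, "lesionlab_segmentation_failure")

#' Binary mask from an iso-valued contour
#'
#' Extracts the iso-contours of `gray` at `iso_value` and fills their
#' interiors. On the pixel grid the region enclosed by the iso-contours is
#' the sublevel set (`dark_low`: pixels at or below the iso value; the
#' lesion is dark) with its holes filled. A constant image has no iso-valued
#' contour, and an iso level below the minimum or at/above the maximum
#' intensity yields no closed contour either; both raise a segmentation
#' failure.
#'
#' @param gray intensity matrix, 0-255.
#' @param iso_value iso level in 0-255.
#' @param polarity `"dark_low"` (foreground at or below iso) or
#'   `"bright_low"` (at or above).
#' @return 0/1 mask matrix, holes filled per connected component.
#' @export
isocontour_mask <- function(gray, iso_value, polarity = c("dark_low", "bright_low")) {
  polarity <- match.arg(polarity)
  stopifnot(iso_value >= 0, iso_value <= 255)
  v <- round(gray)
  if (polarity == "bright_low") {
    v <- 255 - v
    iso_value <- 255 - iso_value
  }
  if (min(v) == max(v))
    segmentation_failure("constant image: no iso-valued contour")
  fg <- v <= iso_value
  if (!any(fg) || all(fg))
    segmentation_failure("iso level crosses no contour")
  lab <- EBImage::bwlabel(fg + 0)
  filled <- EBImage::fillHull(lab)
  (filled > 0) + 0L
}

#' Keep the lesion's connected component
#'
#' Keeps the largest-area 4-connected foreground component (ties broken by
#' centroid distance to the frame center), and fills its holes.
#'
#' @param mask 0/1 mask with at least one foreground pixel.
#' @return 0/1 mask with exactly one hole-free component.
#' @export
select_lesion_component <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) segmentation_failure("empty mask")
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    ctr <- (dim(mask) + 1) / 2
    d2 <- vapply(best, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      sum((colMeans(px) - ctr)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  keep <- (lab == best[1]) + 0
  (EBImage::fillHull(keep) > 0) + 0L
}

#' Segment a dermoscopic image
#'
#' Full persistence-guided chain: grayscale conversion, H0 persistence of
#' the sublevel filtration, lifespan thresholding, contrast enhancement,
#' iso-contouring at the enhanced image's Otsu level, and lesion component
#' selection. Raises a segmentation failure when no plausible lesion
#' emerges (no contour, or selected component below `min_area_frac` of the
#' frame).
#'
#' @param image RGB array (0-255), or a `labeled_image`.
#' @param polarity filtration polarity; lesions are assumed darker than the
#'   surrounding skin by default.
#' @param min_area_frac minimal lesion area as a fraction of the frame below
#'   which segmentation is considered failed.
#' @return 0/1 mask matrix (single hole-free component).
#' @examples
#' les <- make_lesion(lesion_spec(base_radius = 30, seed = 7))
#' m <- segment(les$image)
#' sum(m & les$mask) / sum(m | les$mask)  # close to 1
#' @export
segment <- function(image, polarity = "dark_low", min_area_frac = 0.005) {
  if (inherits(image, "labeled_image")) image <- image$image
  gray <- to_grayscale(image)
  pers <- h0_persistence(gray, polarity)
  thr <- lifespan_threshold(pers)
  enh <- enhance_contrast(gray, pers, thr)
  if (min(enh) == max(enh))
    segmentation_failure("enhanced image is constant: no lesion found")
  iso <- otsu_level(enh)
  mask <- isocontour_mask(enh, iso, polarity)
  mask <- select_lesion_component(mask)
  if (sum(mask) < min_area_frac * length(mask))
    segmentation_failure("selected component too small to be a lesion")
  mask
}

# Otsu threshold of an 8-bit intensity matrix, on the 0-255 scale
otsu_level <- function(gray) {
  im <- EBImage::Image(gray / 255)
  round(EBImage::otsu(im, range = c(0, 1), levels = 256) * 255)
}

#' Segmentation quality control
#'
#' `qc_mask()` applies the failure rules to one mask: failed segmentation,
#' lesion area outside `[min_area_frac, max_area_frac]` of the frame, or
#' contact with two or more image borders (lesion larger than the field of
#' view). `qc_failure_rate()` segments a batch and returns the failing
#' fraction, mirroring how segmentation error rates are assessed on real
#' dermoscopy datasets.
#'
#' @param mask 0/1 matrix, or `NULL` for a failed segmentation.
#' @param min_area_frac,max_area_frac area bounds as fractions of the frame.
#' @return `qc_mask()`: `TRUE` if the mask passes; `qc_failure_rate()`: the
#'   failing fraction, with per-image results in attribute `failed`.
#' @export
qc_mask <- function(mask, min_area_frac = 0.01, max_area_frac = 0.90) {
  if (is.null(mask) || is_segmentation_failure(mask)) return(FALSE)
  a <- sum(mask > 0)
  if (a < min_area_frac * length(mask)) return(FALSE)
  if (a > max_area_frac * length(mask)) return(FALSE)
  borders <- c(any(mask[1, ] > 0), any(mask[nrow(mask), ] > 0),
               any(mask[, 1] > 0), any(mask[, ncol(mask)] > 0))
  if (sum(borders) >= 2) return(FALSE)
  TRUE
}

#' @rdname qc_mask
#' @param masks list of masks (entries may be `NULL` or a caught
#'   segmentation-failure condition), or a list of `labeled_image` /
#'   RGB arrays to segment first.
#' @param segment_first if `TRUE`, entries are images and are segmented
#'   (failures counted) before QC.
#' @export
qc_failure_rate <- function(masks, segment_first = FALSE,
                            min_area_frac = 0.01, max_area_frac = 0.90) {
  stopifnot(length(masks) > 0)
  if (segment_first)
    masks <- lapply(masks, function(im)
      tryCatch(segment(im), lesionlab_segmentation_failure = function(e) e))
  ok <- vapply(masks, qc_mask, logical(1),
               min_area_frac = min_area_frac, max_area_frac = max_area_frac)
  structure(mean(!ok), failed = !ok)
}
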