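#' @name image-io
#' @title Raster image containers and I/O
#'
#' @description
#' Images are plain R arrays: an RGB image is an `H x W x 3` numeric array
#' with values in 0-255, a grayscale image an `H x W` matrix in 0-255, and a
#' binary mask an `H x W` matrix in \{0, 1\}. Row 1 is the top image row.
#' PNG is the on-disk format; masks are written as single-channel 0/255.
NULL

#' @rdname image-io
#' @param path PNG file path.
#' @return `read_image()` returns an RGB array, `read_mask()` a 0/1 matrix.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' @rdname image-io
#' @param image RGB array (0-255).
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname image-io
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0.5) + 0L
}

#' @rdname image-io
#' @param mask binary 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG((mask > 0) + 0, path)
  invisible(path)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest
#' integer gray level. This is the intensity image on which the sublevel-set
#' persistence filtration runs.
#'
#' @param image `H x W x 3` RGB array with values in 0-255.
#' @return `H x W` integer-valued matrix in 0-255.
#' @examples
#' img <- array(c(100, 200, 50), dim = c(1, 1, 3))
#' to_grayscale(img)  # 153
#' @export
to_grayscale <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(round(g), dim(image)[1], dim(image)[2])
}

# modal intensity of an integer-valued gray image
modal_intensity <- function(gray) {
  tab <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  which.max(tab) - 1L
}

# single largest 4-connected foreground component count check
count_components <- function(mask) {
  max(EBImage::bwlabel(mask))
}
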