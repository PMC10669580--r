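#' The six-color dermoscopy palette
#'
#' Canonical lesion colors used in clinical dermoscopy scoring: white, black,
#' red, light brown, dark brown and blue-gray. Detected dominant colors are
#' snapped to this palette by nearest RGB distance, and color density is
#' reported per palette entry. The RGB anchors are package configuration,
#' not clinical constants; override by passing a modified palette.
#'
#' @param overrides optional named list of `c(r, g, b)` triplets (0-255)
#'   replacing individual palette anchors.
#' @return a 6-row data.frame with columns `name`, `r`, `g`, `b`.
#' @examples
#' dermoscopy_palette()
#' @export
dermoscopy_palette <- function(overrides = NULL) {
  pal <- data.frame(
    name = c("white", "black", "red", "light_brown", "dark_brown", "blue_gray"),
    r = c(255, 0, 255, 205, 101, 113),
    g = c(255, 0, 0, 133, 67, 128),
    b = c(255, 0, 0, 63, 33, 147),
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      i <- match(nm, pal$name)
      if (is.na(i)) stop("unknown palette color: ", nm)
      v <- overrides[[nm]]
      stopifnot(length(v) == 3, all(v >= 0), all(v <= 255))
      pal[i, c("r", "g", "b")] <- as.numeric(v)
    }
  }
  pal
}

#' Snap an RGB triplet to the nearest dermoscopy palette color
#'
#' Minimum Euclidean distance in RGB space; exact ties resolved by palette
#' order (white, black, red, light_brown, dark_brown, blue_gray).
#'
#' @param color numeric triplet (or n x 3 matrix) of RGB values in 0-255.
#' @param palette palette data.frame, see [dermoscopy_palette()].
#' @return character vector of palette color names.
#' @examples
#' palette_assign(c(255, 255, 255))
#' palette_assign(c(250, 5, 5))
#' @export
palette_assign <- function(color, palette = dermoscopy_palette()) {
  m <- if (is.matrix(color)) color else matrix(color, ncol = 3, byrow = TRUE)
  stopifnot(ncol(m) == 3, all(is.finite(m)))
  anchors <- as.matrix(palette[, c("r", "g", "b")])
  idx <- apply(m, 1, function(p) {
    d2 <- colSums((t(anchors) - p)^2)
    which.min(d2)  # which.min takes the first minimum: palette-order ties
  })
  palette$name[idx]
}
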