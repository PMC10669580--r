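#' Orientation of a lesion's major axis
#'
#' Angle of the largest-eigenvalue eigenvector of the second central moment
#' matrix of the foreground pixel coordinates, measured counterclockwise
#' from the horizontal (image x) axis with y pointing up, in (-90, 90]
#' degrees. Nearly isotropic masks (a disk) have no meaningful major axis:
#' the angle is 0 with attribute `isotropic = TRUE`.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @param iso_tol relative anisotropy below which the mask is flagged
#'   isotropic.
#' @return angle in degrees with attribute `isotropic`.
#' @export
principal_axis_angle <- function(mask, iso_tol = 1e-3) {
  px <- which(mask > 0, arr.ind = TRUE)
  stopifnot(nrow(px) > 0)
  x <- px[, 2]; y <- -px[, 1]  # y up
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2); mu02 <- mean((y - my)^2)
  mu11 <- mean((x - mx) * (y - my))
  denom <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (denom < iso_tol * (mu20 + mu02))
    return(structure(0, isotropic = TRUE))
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(ang, isotropic = FALSE)
}

#' Recenter and rotate a lesion into a standard pose
#'
#' Translates the mask centroid to the center of a square canvas large
#' enough that no foreground pixel is lost, and rotates by minus the major
#' axis angle so the longer axis lies horizontal. The remaining 180-degree
#' ambiguity is resolved by requiring the heavier half of the lesion (more
#' foreground pixels) to lie in the upper half-plane (sectors 1-4). Masks
#' are resampled nearest-neighbor (stays binary), images bilinear with the
#' border-median color as fill.
#'
#' @param image RGB array (0-255).
#' @param mask 0/1 matrix, same frame.
#' @return a `normalized_lesion`: list with `image`, `mask`,
#'   `rotation_deg` (rotation applied, degrees counterclockwise),
#'   `centroid_shift` (c(row, col) translation applied), `center` (canvas
#'   center pixel).
#' @export
normalize_pose <- function(image, mask) {
  stopifnot(length(dim(image)) == 3, all(dim(image)[1:2] == dim(mask)))
  px <- which(mask > 0, arr.ind = TRUE)
  stopifnot(nrow(px) > 0)
  centroid <- colMeans(px)  # (row, col)
  ang <- principal_axis_angle(mask)
  theta <- if (isTRUE(attr(ang, "isotropic"))) 0 else as.numeric(ang)

  rmax <- sqrt(max((px[, 1] - centroid[1])^2 + (px[, 2] - centroid[2])^2))
  D <- 2L * (ceiling(rmax) + 4L) + 1L  # odd canvas, lesion always fits
  ctr <- (D + 1) / 2

  out <- pose_resample(image, mask, centroid, theta, D, ctr)

  # 180-degree disambiguation: heavier half up
  vgrid <- -(matrix(rep(seq_len(D), D), D, D) - ctr)
  upper <- sum(out$mask[vgrid > 0])
  lower <- sum(out$mask[vgrid < 0])
  if (lower > upper) {
    theta <- theta + 180
    out$mask <- out$mask[D:1, D:1]
    out$image <- out$image[D:1, D:1, , drop = FALSE]
  }

  structure(list(image = out$image, mask = out$mask,
                 rotation_deg = -theta,
                 centroid_shift = c(ctr, ctr) - centroid,
                 center = ctr),
            class = "normalized_lesion")
}

# inverse-mapped resampling shared by normalize_pose: rotate by -theta about
# the centroid and recenter on a D x D canvas
pose_resample <- function(image, mask, centroid, theta, D, ctr) {
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  u <- matrix(rep(seq_len(D), each = D), D, D) - ctr   # x offset
  v <- -(matrix(rep(seq_len(D), D), D, D) - ctr)       # y-up offset
  col_src <- centroid[2] + co * u - si * v
  row_src <- centroid[1] - (si * u + co * v)

  # nearest neighbor for the mask
  rn <- round(row_src); cn <- round(col_src)
  ok <- rn >= 1 & rn <= nrow(mask) & cn >= 1 & cn <= ncol(mask)
  m_out <- matrix(0L, D, D)
  m_out[ok] <- mask[cbind(rn[ok], cn[ok])]

  # bilinear for the image, border-median fill
  H <- dim(image)[1]; W <- dim(image)[2]
  r0 <- floor(as.vector(row_src)); c0 <- floor(as.vector(col_src))
  fr <- as.vector(row_src) - r0; fc <- as.vector(col_src) - c0
  r0c <- pmin(pmax(r0, 1), H); r1c <- pmin(pmax(r0 + 1, 1), H)
  c0c <- pmin(pmax(c0, 1), W); c1c <- pmin(pmax(c0 + 1, 1), W)
  inb <- as.vector(row_src >= 1 & row_src <= H &
                   col_src >= 1 & col_src <= W)
  img_out <- array(0, dim = c(D, D, 3))
  for (ch in 1:3) {
    plane <- image[, , ch]
    fill <- median(c(plane[1, ], plane[H, ], plane[, 1], plane[, W]))
    val <- plane[cbind(r0c, c0c)] * (1 - fr) * (1 - fc) +
           plane[cbind(r1c, c0c)] * fr * (1 - fc) +
           plane[cbind(r0c, c1c)] * (1 - fr) * fc +
           plane[cbind(r1c, c1c)] * fr * fc
    val[!inb] <- fill
    img_out[, , ch] <- matrix(val, D, D)
  }
  list(image = round(img_out), mask = m_out)
}

#' Divide a normalized lesion into eight angular sectors
#'
#' Eight 45-degree sectors about the canvas center, sector 1 starting at the
#' positive horizontal axis and proceeding counterclockwise; sector `k`
#' covers angles in `[45 (k - 1), 45 k)` degrees, so a pixel exactly on a
#' boundary ray belongs to the sector the ray opens. With this half-open
#' convention sectors `i` and `i + 4` are exact point reflections of each
#' other through the center — the property the opposite-region asymmetry
#' comparisons rely on.
#'
#' @param norm a `normalized_lesion` from [normalize_pose()].
#' @return a `sector_partition`: integer matrix with values 1-8 on the mask
#'   foreground and 0 on the background.
#' @export
eight_sectors <- function(norm) {
  stopifnot(inherits(norm, "normalized_lesion"))
  mask <- norm$mask
  D <- nrow(mask); ctr <- norm$center
  u <- matrix(rep(seq_len(D), each = D), D, D) - ctr
  v <- -(matrix(rep(seq_len(D), D), D, D) - ctr)
  # exact integer comparisons (no atan2 rounding at the 45-degree rays):
  # sector k covers [45 (k - 1), 45 k)
  sec <- matrix(0L, D, D)
  sec[u > 0 & v >= 0 & v < u] <- 1L
  sec[v > 0 & u > 0 & v >= u] <- 2L
  sec[v > 0 & u <= 0 & -u < v] <- 3L
  sec[v > 0 & u < 0 & -u >= v] <- 4L
  sec[u < 0 & v <= 0 & v > u] <- 5L
  sec[v < 0 & u < 0 & v <= u] <- 6L
  sec[v < 0 & u >= 0 & u < -v] <- 7L
  sec[v < 0 & u > 0 & u >= -v] <- 8L
  sec[u == 0 & v == 0] <- 1L  # center pixel: angle undefined, lowest id
  sec <- sec * (mask > 0)
  structure(sec, class = c("sector_partition", class(sec)))
}
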