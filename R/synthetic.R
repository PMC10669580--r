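#' Specification of a synthetic dermoscopic lesion
#'
#' A synthetic lesion is a star-shaped region whose boundary follows the
#' radial-harmonic model
#' \deqn{r(\theta) = R (1 + \sum_k a_k \cos(k\theta + \phi_k)), \quad k = 2..K,}
#' with phases drawn from the seed. Harmonic amplitudes control border
#' irregularity, the interior is painted with dermoscopy palette colors in
#' angular wedges around a center displaced by `asymmetry_shift` (color
#' asymmetry), and i.i.d. Gaussian pixel noise is added per channel. This
#' gives analytic control over exactly the shape/color properties the
#' ABCD-rule features measure, and a ground-truth mask for free.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param base_radius mean radius R in pixels.
#' @param harmonic_amplitudes named or positional numeric vector of
#'   amplitudes `a_k` for harmonics `k = 2, 3, ...` (first element is k = 2).
#' @param asymmetry_shift displacement of the color-wedge center, as a
#'   fraction of `base_radius`.
#' @param palette_weights non-negative weights over the six palette colors
#'   (named, any subset; missing colors get weight 0); normalized to sum 1.
#' @param background_rgb skin background color triplet (0-255).
#' @param noise_sd Gaussian pixel noise standard deviation, gray levels.
#' @param seed integer seed controlling phases, wedge placement and noise.
#' @return a `lesion_spec` object (validated list).
#' @examples
#' sp <- lesion_spec(base_radius = 30, harmonic_amplitudes = c(0.2, 0, 0.1))
#' les <- make_lesion(sp)
#' sum(les$mask)
#' @export
lesion_spec <- function(image_size = c(128, 128),
                        base_radius = 32,
                        harmonic_amplitudes = numeric(0),
                        asymmetry_shift = 0,
                        palette_weights = c(dark_brown = 1),
                        background_rgb = c(224, 172, 138),
                        noise_sd = 0,
                        seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            base_radius >= 4, all(harmonic_amplitudes >= 0),
            asymmetry_shift >= 0, asymmetry_shift <= 1,
            length(background_rgb) == 3, noise_sd >= 0)
  pal <- dermoscopy_palette()
  w <- setNames(numeric(nrow(pal)), pal$name)
  if (is.null(names(palette_weights))) {
    stopifnot(length(palette_weights) == 6)
    w[] <- palette_weights
  } else {
    stopifnot(all(names(palette_weights) %in% pal$name))
    w[names(palette_weights)] <- palette_weights
  }
  if (any(w < 0) || sum(w) <= 0) stop("palette weights must be >= 0, sum > 0")
  w <- w / sum(w)
  stopifnot(abs(sum(w) - 1) < 1e-9)

  excursion <- base_radius * (1 + sum(harmonic_amplitudes))
  if (excursion >= min(image_size) / 2)
    stop("radial excursion (", round(excursion, 1),
         " px) exits the frame; reduce base_radius or amplitudes")

  structure(list(
    image_size = as.integer(image_size),
    base_radius = base_radius,
    harmonic_amplitudes = as.numeric(harmonic_amplitudes),
    asymmetry_shift = asymmetry_shift,
    palette_weights = w,
    background_rgb = as.numeric(background_rgb),
    noise_sd = noise_sd,
    seed = as.integer(seed)), class = "lesion_spec")
}

#' Render a synthetic lesion image with its ground-truth mask
#'
#' @param spec a [lesion_spec()].
#' @param label optional class label (`"benign"` or `"malignant"`) carried
#'   through to the returned object.
#' @return a `labeled_image`: list with `image` (`H x W x 3`, 0-255), `mask`
#'   (0/1 matrix, one 4-connected component), `label`, `spec`.
#' @export
make_lesion <- function(spec, label = NA_character_) {
  stopifnot(inherits(spec, "lesion_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  amps <- spec$harmonic_amplitudes
  K <- length(amps)

  with_seed(spec$seed, {
    phases <- runif(K, 0, 2 * pi)
    psi <- runif(1, 0, 2 * pi)     # direction of the color-center shift
    omega <- runif(1, 0, 2 * pi)   # rotation of the color wedges

    col_idx <- matrix(rep(seq_len(W), each = H), H, W)
    row_idx <- matrix(rep(seq_len(H), W), H, W)
    dx <- col_idx - cx
    dy <- row_idx - cy
    theta <- atan2(dy, dx)
    rr <- sqrt(dx^2 + dy^2)

    rb <- spec$base_radius
    r_theta <- rep(1, length(theta))
    for (k in seq_len(K))
      r_theta <- r_theta + amps[k] * cos((k + 1) * theta + phases[k])
    r_theta <- rb * r_theta
    mask <- (rr <= r_theta) + 0L
    dim(mask) <- c(H, W)

    # color wedges about the displaced center
    ccx <- cx + spec$asymmetry_shift * rb * cos(psi)
    ccy <- cy + spec$asymmetry_shift * rb * sin(psi)
    th2 <- (atan2(row_idx - ccy, col_idx - ccx) + omega) %% (2 * pi)
    active <- which(spec$palette_weights > 0)
    cuts <- 2 * pi * cumsum(spec$palette_weights[active])
    wedge <- findInterval(th2, cuts, left.open = TRUE) + 1L
    wedge[wedge > length(active)] <- length(active)

    pal <- dermoscopy_palette()
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_rgb[ch], H, W)
      anchors <- pal[active, c("r", "g", "b")][[ch]]
      plane[mask == 1] <- anchors[wedge[mask == 1]]
      img[, , ch] <- plane
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- pmin(pmax(round(img), 0), 255)

    structure(list(image = img, mask = mask, label = label, spec = spec),
              class = "labeled_image")
  })
}

#' Default generator presets for the two diagnostic classes
#'
#' Ranges from which per-image lesion specs are drawn. Benign lesions:
#' nearly elliptical borders (few, small radial harmonics), little color
#' asymmetry, 1-2 palette colors. Malignant: more and larger harmonics,
#' larger asymmetry shift, 3-4 palette colors. The presets deliberately
#' overlap so the two classes are separable but not trivially so. All
#' entries are configuration; pass modified lists to [make_dataset()].
#'
#' @return a named list of ranges (`radius`, `n_harmonics`, `amp`, `asym`,
#'   `n_colors`, `colors`, `noise_sd`).
#' @export
benign_preset <- function() {
  list(radius = c(25, 40), n_harmonics = c(1, 3), amp = c(0, 0.08),
       asym = c(0, 0.10), n_colors = c(1, 2),
       colors = c("light_brown", "dark_brown", "red", "blue_gray", "black"),
       noise_sd = 8)
}

#' @rdname benign_preset
#' @export
malignant_preset <- function() {
  list(radius = c(25, 40), n_harmonics = c(3, 6), amp = c(0.05, 0.18),
       asym = c(0.05, 0.25), n_colors = c(3, 4),
       colors = c("light_brown", "dark_brown", "red", "blue_gray", "black"),
       noise_sd = 8)
}

# draw one lesion_spec from a preset range list
draw_spec <- function(ranges, image_size, seed) {
  with_seed(seed, {
    rad <- runif(1, ranges$radius[1], ranges$radius[2])
    nh <- sample(ranges$n_harmonics[1]:ranges$n_harmonics[2], 1)
    ks <- sort(sample(2:8, nh))
    amps <- numeric(7)  # slots for k = 2..8
    amps[ks - 1] <- runif(nh, ranges$amp[1], ranges$amp[2])
    # keep the lesion star-shaped and inside the frame
    if (sum(amps) > 0.40) amps <- amps * 0.40 / sum(amps)
    # keep the maximal excursion inside the frame for any frame size
    rad <- min(rad, (min(image_size) / 2 - 2) / (1 + sum(amps)))
    nc <- sample(ranges$n_colors[1]:ranges$n_colors[2], 1)
    cols <- sample(ranges$colors, nc)
    wts <- runif(nc, 0.3, 1)
    lesion_spec(image_size = image_size,
                base_radius = rad,
                harmonic_amplitudes = amps,
                asymmetry_shift = runif(1, ranges$asym[1], ranges$asym[2]),
                palette_weights = setNames(wts, cols),
                noise_sd = ranges$noise_sd,
                seed = with_seed(seed + 1L, sample.int(.Machine$integer.max %/% 2, 1)))
  })
}

#' Generate a labeled synthetic dataset with manifest
#'
#' Draws `n_benign` + `n_malignant` lesions from the class presets. When
#' `dir` is given, images and 0/255 masks are written as PNG and a manifest
#' CSV (`id,path,mask_path,label,source`) is written alongside; otherwise
#' rendered images stay in memory and paths are empty.
#'
#' @param n_benign,n_malignant per-class image counts.
#' @param benign_ranges,malignant_ranges preset range lists, see
#'   [benign_preset()].
#' @param seed master seed; every image gets a derived child seed.
#' @param image_size frame size `c(H, W)`.
#' @param source source tag recorded in the manifest (e.g. `"DB1"`).
#' @param dir optional output directory.
#' @return list with `images` (list of `labeled_image`) and `manifest`
#'   (data.frame).
#' @export
make_dataset <- function(n_benign, n_malignant,
                         benign_ranges = benign_preset(),
                         malignant_ranges = malignant_preset(),
                         seed = 1L,
                         image_size = c(128, 128),
                         source = "DB1",
                         dir = NULL) {
  stopifnot(n_benign > 0, n_malignant > 0)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  seeds <- spawn_seeds(seed, length(labels))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  images <- vector("list", length(labels))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rgs <- if (labels[i] == "benign") benign_ranges else malignant_ranges
    sp <- draw_spec(rgs, image_size, seeds[i])
    li <- make_lesion(sp, label = labels[i])
    id <- sprintf("%s_%s_%04d", source, labels[i],
                  if (labels[i] == "benign") i else i - n_benign)
    path <- mask_path <- ""
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(id, ".png"))
      mask_path <- file.path(dir, paste0(id, "_mask.png"))
      write_image(li$image, path)
      write_mask(li$mask, mask_path)
    }
    images[[i]] <- li
    rows[[i]] <- data.frame(id = id, path = path, mask_path = mask_path,
                            label = labels[i], source = source,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(images = images, manifest = manifest)
}
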