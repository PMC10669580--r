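#' Pipeline configuration
#'
#' Central, validated configuration for [run_all()]. Every constant the
#' method leaves open lives here: pool sizes of the simulated sources,
#' generator presets, segmentation polarity and QC bounds, color histogram
#' bins, balancing and split fractions, classifier choice and the master
#' seed. Unknown keys are rejected.
#'
#' The default study simulates three sources mirroring the roles of the
#' real corpora: two training sources (DB1, imbalanced toward benign, and a
#' small DB2) and a disjoint test source (DB3) with a 4:1 benign:malignant
#' ratio, sized so the 65% benign sampling yields ten balanced subsets of
#' 400 records and a 200-image test set.
#'
#' @param ... key = value overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
lesionlab_config <- function(...) {
  cfg <- list(
    seed = 1L,
    image_size = c(128, 128),
    db1_benign = 277, db1_malignant = 170,
    db2_benign = 20, db2_malignant = 30,
    test_benign = 160, test_malignant = 40,
    benign_ranges = benign_preset(),
    malignant_ranges = malignant_preset(),
    polarity = "dark_low",
    qc_min_area = 0.01, qc_max_area = 0.90,
    histogram_bins = 64,
    kmeans_k = 3,
    palette = dermoscopy_palette(),
    n_subsets = 10, benign_fraction = 0.65, train_fraction = 0.70,
    model = "boosted_tree", model_params = list(),
    write_images = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Run the full study end to end
#'
#' Simulate the three sources, segment every image with the
#' persistence-guided chain, apply QC (images failing segmentation or QC
#' are dropped from the study, and their rate reported), extract features,
#' build the balanced subsets, train and evaluate across them, and write
#' every stage's outputs under `out_dir`: the resolved config
#' (`config.yaml`), `manifest.csv`, `features.csv`, `qc.csv`, split
#' manifests under `splits/`, per-subset `metrics.json` and a
#' `summary.json`. Reruns with the same config reproduce identical result
#' files.
#'
#' @param config a `pipeline_config`, see [lesionlab_config()].
#' @param out_dir results directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `manifest`, `features`, `qc`,
#'   `balanced`, `result` (a `run_summary`) and `out_dir`.
#' @export
run_all <- function(config = lesionlab_config(), out_dir, quiet = FALSE) {
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  yaml::write_yaml(config_for_log(config), file.path(out_dir, "config.yaml"))

  img_dir <- if (isTRUE(config$write_images))
    file.path(out_dir, "images") else NULL
  say("simulating sources")
  seeds <- spawn_seeds(config$seed, 3, stream = 7L)
  db1 <- make_dataset(config$db1_benign, config$db1_malignant,
                      config$benign_ranges, config$malignant_ranges,
                      seed = seeds[1], image_size = config$image_size,
                      source = "DB1", dir = img_dir)
  db2 <- make_dataset(config$db2_benign, config$db2_malignant,
                      config$benign_ranges, config$malignant_ranges,
                      seed = seeds[2], image_size = config$image_size,
                      source = "DB2", dir = img_dir)
  db3 <- make_dataset(config$test_benign, config$test_malignant,
                      config$benign_ranges, config$malignant_ranges,
                      seed = seeds[3], image_size = config$image_size,
                      source = "DB3", dir = img_dir)
  images <- c(db1$images, db2$images, db3$images)
  manifest <- rbind(db1$manifest, db2$manifest, db3$manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  say("segmenting ", nrow(manifest), " images")
  masks <- lapply(images, function(li)
    tryCatch(segment(li$image, polarity = config$polarity),
             lesionlab_segmentation_failure = function(e) e))
  ok <- vapply(masks, qc_mask, logical(1),
               min_area_frac = config$qc_min_area,
               max_area_frac = config$qc_max_area)
  qc <- data.frame(id = manifest$id, label = manifest$label,
                   source = manifest$source, qc_pass = ok)
  write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  say("QC failure rate: ", sprintf("%.1f%%", 100 * mean(!ok)))

  say("extracting features")
  feat_seeds <- spawn_seeds(config$seed, nrow(manifest), stream = 8L)
  feats <- lapply(which(ok), function(i) {
    f <- extract_features(images[[i]]$image, masks[[i]],
                          palette = config$palette, seed = feat_seeds[i])
    cbind(data.frame(id = manifest$id[i], label = manifest$label[i],
                     source = manifest$source[i]), f)
  })
  features <- do.call(rbind, feats)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  say("balancing and splitting")
  train_records <- manifest[ok & manifest$source != "DB3",
                            c("id", "label", "source")]
  test_manifest <- manifest[ok & manifest$source == "DB3",
                            c("id", "label", "source")]
  balanced <- balance_datasets(train_records,
                               n_subsets = config$n_subsets,
                               benign_fraction = config$benign_fraction,
                               seed = config$seed)
  write_splits(balanced, file.path(out_dir, "splits"),
               train_fraction = config$train_fraction, seed = config$seed)

  say("training ", config$model, " across ", config$n_subsets, " subsets")
  result <- run_experiment(features, balanced, test_manifest,
                           model = config$model, params = config$model_params,
                           train_fraction = config$train_fraction,
                           seed = config$seed)
  jsonlite::write_json(result$per_subset, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(model = config$model,
         qc_failure_rate = mean(!ok),
         summary = result$summary),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, features = features, qc = qc,
                 balanced = balanced, result = result, out_dir = out_dir))
}

# palette / preset entries flattened so the logged config is plain YAML
config_for_log <- function(config) {
  cfg <- config
  cfg$palette <- as.list(setNames(
    sprintf("%d,%d,%d", config$palette$r, config$palette$g,
            config$palette$b),
    config$palette$name))
  cfg
}

#' Persistence bars as a CSV diagram
#'
#' Writes `birth,death` rows, with the literal `inf` for the essential
#' bar's death, the conventional text form of a persistence diagram.
#'
#' @param bars an `h0_persistence` object.
#' @param path output CSV path.
#' @export
write_bars <- function(bars, path) {
  stopifnot(inherits(bars, "h0_persistence"))
  d <- bars$bars[, c("birth", "death")]
  d$death <- ifelse(is.finite(d$death), as.character(d$death), "inf")
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Feature table for a batch of images
#'
#' Segments each image (unless ground-truth masks are supplied) and
#' extracts the raw feature record; images failing segmentation or QC are
#' skipped and reported in the `skipped` attribute.
#'
#' @param images list of `labeled_image` objects (or RGB arrays).
#' @param manifest data.frame with `id`, `label` (and optionally `source`)
#'   aligned with `images`.
#' @param use_truth_masks take masks from the `labeled_image`s instead of
#'   segmenting.
#' @param config a `pipeline_config` for the segmentation/feature knobs.
#' @return data.frame `id`, `label`, `source`, features; attribute
#'   `skipped` lists dropped ids.
#' @export
build_feature_table <- function(images, manifest, use_truth_masks = FALSE,
                                config = lesionlab_config()) {
  stopifnot(length(images) == nrow(manifest))
  seeds <- spawn_seeds(config$seed, nrow(manifest), stream = 8L)
  rows <- list(); skipped <- character(0)
  for (i in seq_along(images)) {
    li <- images[[i]]
    img <- if (inherits(li, "labeled_image")) li$image else li
    mask <- if (use_truth_masks) li$mask else
      tryCatch(segment(img, polarity = config$polarity),
               lesionlab_segmentation_failure = function(e) e)
    if (!qc_mask(mask, config$qc_min_area, config$qc_max_area)) {
      skipped <- c(skipped, manifest$id[i])
      next
    }
    f <- extract_features(img, mask, palette = config$palette,
                          seed = seeds[i])
    src <- if ("source" %in% names(manifest)) manifest$source[i]
           else NA_character_
    rows[[length(rows) + 1]] <- cbind(
      data.frame(id = manifest$id[i], label = manifest$label[i],
                 source = src), f)
  }
  structure(do.call(rbind, rows), skipped = skipped)
}
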