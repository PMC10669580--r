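#' Balanced dataset shuffles
#'
#' Reproduces the class-balancing protocol used when benign images heavily
#' outnumber malignant ones: each of `n_subsets` balanced datasets is built
#' as an independent uniform sample (without replacement) of
#' `round(benign_fraction * |DB1 benign|)` DB1 benign records — rounding
#' half away from zero — plus all DB1 malignant and all DB2 records. DB3
#' records (the disjoint test source) are excluded from every subset. All
#' subsets have identical size; only the sampled benign portion varies.
#'
#' @param records data.frame with columns `id`, `label`
#'   (`benign`/`malignant`) and `source` (`DB1`, `DB2`, `DB3`); ids unique.
#' @param n_subsets number of balanced shuffles.
#' @param benign_fraction fraction of the DB1 benign pool sampled per
#'   subset.
#' @param seed master seed; each subset samples under its own derived seed.
#' @return a `balanced_subsets` object: list with `subsets` (list of
#'   data.frames), `seed`, `benign_fraction`, `sample_size`.
#' @export
balance_datasets <- function(records, n_subsets = 10, benign_fraction = 0.65,
                             seed = 1L) {
  stopifnot(all(c("id", "label", "source") %in% names(records)),
            !anyDuplicated(records$id),
            all(records$label %in% c("benign", "malignant")),
            n_subsets >= 1, benign_fraction > 0, benign_fraction <= 1)
  pool_b1b <- which(records$source == "DB1" & records$label == "benign")
  fixed <- which(records$source != "DB3" &
                 !(records$source == "DB1" & records$label == "benign"))
  if (length(pool_b1b) == 0) stop("no DB1 benign records to sample from")
  n_sample <- round_half_up(benign_fraction * length(pool_b1b))
  if (n_sample > length(pool_b1b))
    stop("benign pool smaller than requested sample")
  seeds <- spawn_seeds(seed, n_subsets, stream = 1L)
  subsets <- lapply(seq_len(n_subsets), function(k) {
    take <- with_seed(seeds[k], sort(sample(pool_b1b, n_sample)))
    records[sort(c(take, fixed)), , drop = FALSE]
  })
  structure(list(subsets = subsets, seed = as.integer(seed),
                 benign_fraction = benign_fraction, sample_size = n_sample),
            class = "balanced_subsets")
}

#' @export
print.balanced_subsets <- function(x, ...) {
  cat(length(x$subsets), "balanced subsets of",
      nrow(x$subsets[[1]]), "records (", x$sample_size,
      "sampled benign each )\n")
  invisible(x)
}

#' Stratified train/validation split
#'
#' Splits a subset into train and validation with `|train| =
#' round(train_fraction * n)` (round half away from zero), stratified by
#' label: per-class training counts are the class floors topped up by
#' largest fractional remainder until the overall target is met, so class
#' proportions match the subset's within one record per class.
#'
#' @param subset data.frame with a `label` column.
#' @param train_fraction fraction of records in the training part.
#' @param seed RNG seed.
#' @return list with `train` and `validation` data.frames (disjoint, union
#'   is the subset).
#' @export
train_val_split <- function(subset, train_fraction = 0.70, seed = 1L) {
  stopifnot(nrow(subset) > 0, "label" %in% names(subset),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(subset)
  target <- round_half_up(train_fraction * n)
  labs <- unique(subset$label)
  per <- vapply(labs, function(l) sum(subset$label == l), numeric(1))
  quota <- train_fraction * per
  take <- floor(quota)
  rem <- target - sum(take)
  if (rem > 0) {
    ord <- order(-(quota - take), seq_along(labs))  # ties by class order
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(labs), function(i) {
      rows <- which(subset$label == labs[i])
      sample(rows, take[i])
    }))
  })
  idx <- sort(idx)
  list(train = subset[idx, , drop = FALSE],
       validation = subset[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Audit the balancing protocol's arithmetic
#'
#' Pure count arithmetic of the balancing and splitting protocol: from raw
#' per-source class counts it derives the combined training-pool size, the
#' per-subset benign sample, the balanced subset size, and the stratified
#' 70/30 train/validation sizes. No image data involved.
#'
#' @param db1_benign,db1_malignant,db2_benign,db2_malignant raw counts of
#'   the two training sources.
#' @param benign_fraction fraction of DB1 benign sampled per subset.
#' @param train_fraction training share of each balanced subset.
#' @return list of derived counts.
#' @examples
#' audit_counts(14830, 9281, 667, 344)
#' @export
audit_counts <- function(db1_benign, db1_malignant, db2_benign, db2_malignant,
                         benign_fraction = 0.65, train_fraction = 0.70) {
  stopifnot(db1_benign >= 0, db1_malignant >= 0,
            db2_benign >= 0, db2_malignant >= 0)
  combined <- db1_benign + db1_malignant + db2_benign + db2_malignant
  benign_sampled <- round_half_up(benign_fraction * db1_benign)
  subset_size <- benign_sampled + db1_malignant + db2_benign + db2_malignant
  train_size <- round_half_up(train_fraction * subset_size)
  list(combined_total = combined,
       benign_sampled_per_subset = benign_sampled,
       subset_size = subset_size,
       train_size = train_size,
       validation_size = subset_size - train_size)
}

#' Write split manifests to disk
#'
#' One `subset_<k>_train.csv` / `subset_<k>_val.csv` pair per balanced
#' subset.
#'
#' @param balanced a `balanced_subsets` object.
#' @param dir output directory.
#' @param train_fraction,seed forwarded to [train_val_split()]; each subset
#'   splits under its own derived seed.
#' @return invisibly, the list of per-subset splits.
#' @export
write_splits <- function(balanced, dir, train_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(balanced, "balanced_subsets"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds <- spawn_seeds(seed, length(balanced$subsets), stream = 2L)
  splits <- lapply(seq_along(balanced$subsets), function(k) {
    sp <- train_val_split(balanced$subsets[[k]], train_fraction, seeds[k])
    write.csv(sp$train, file.path(dir, sprintf("subset_%d_train.csv", k)),
              row.names = FALSE)
    write.csv(sp$validation, file.path(dir, sprintf("subset_%d_val.csv", k)),
              row.names = FALSE)
    sp
  })
  invisible(splits)
}
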