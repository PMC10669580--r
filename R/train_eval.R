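#' Train a lesion classifier on a feature table
#'
#' The reference model is a gradient-boosted ensemble of shallow decision
#' trees (100 trees of depth 3, shrinkage 0.1), the family that performed
#' best among the classical classifiers compared for this task; KNN, SVM
#' and a single decision tree are available as comparators. All models are
#' deterministic given the seed.
#'
#' @param features data.frame or matrix of numeric feature columns (any
#'   `id` / `label` / `source` columns are dropped automatically).
#' @param labels factor or character vector, `benign` / `malignant`.
#' @param model one of `"boosted_tree"`, `"knn"`, `"svm"`,
#'   `"decision_tree"`.
#' @param params optional named list of model hyperparameters overriding
#'   the defaults (`nrounds`, `max_depth`, `eta` for boosting; `k` for KNN;
#'   `cost` for SVM; `cp` for the tree).
#' @param seed RNG seed.
#' @return a `lesion_classifier` object.
#' @export
train_classifier <- function(features, labels,
                             model = c("boosted_tree", "knn", "svm",
                                       "decision_tree"),
                             params = list(), seed = 1L) {
  model <- match.arg(model)
  x <- feature_matrix(features)
  y <- factor(as.character(labels), levels = c("benign", "malignant"))
  stopifnot(nrow(x) == length(y), !anyNA(y), all(is.finite(x)))
  if (length(unique(y)) < 2) stop("training data holds a single class")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")

  fit <- with_seed(seed, switch(model,
    boosted_tree = {
      p <- modifyList(list(nrounds = 100, max_depth = 3, eta = 0.1), params)
      dm <- xgboost::xgb.DMatrix(x, label = as.integer(y == "malignant"),
                                 nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth, eta = p$eta,
                      nthread = 1, seed = as.integer(seed)),
        data = dm, nrounds = p$nrounds, verbose = 0)
    },
    knn = {
      p <- modifyList(list(k = 7), params)
      e1071::gknn(x, y, k = p$k)
    },
    svm = {
      p <- modifyList(list(cost = 1), params)
      e1071::svm(x, y, kernel = "radial", cost = p$cost, probability = FALSE)
    },
    decision_tree = {
      p <- modifyList(list(cp = 0.01), params)
      d <- data.frame(x, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., data = d, method = "class",
                   control = rpart::rpart.control(cp = p$cp))
    }))
  structure(list(model = model, fit = fit, feature_names = colnames(x),
                 seed = as.integer(seed)),
            class = "lesion_classifier")
}

# strip non-numeric bookkeeping columns and fix column order
feature_matrix <- function(features, names = NULL) {
  if (is.matrix(features)) features <- as.data.frame(features)
  drop <- intersect(c("id", "label", "source", "path", "mask_path"),
                    base::names(features))
  x <- features[, setdiff(base::names(features), drop), drop = FALSE]
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(names)) {
    if (!all(names %in% colnames(x)))
      stop("feature schema mismatch: missing ",
           paste(setdiff(names, colnames(x)), collapse = ", "))
    x <- x[, names, drop = FALSE]
  }
  x
}

#' @rdname train_classifier
#' @param object fitted `lesion_classifier`.
#' @param newdata feature table with the training schema.
#' @param ... unused.
#' @return `predict()`: character vector of predicted labels.
#' @export
predict.lesion_classifier <- function(object, newdata, ...) {
  if (NROW(newdata) == 0) return(character(0))
  x <- feature_matrix(newdata, names = object$feature_names)
  out <- switch(object$model,
    boosted_tree = ifelse(predict(object$fit, x) > 0.5,
                          "malignant", "benign"),
    knn = as.character(predict(object$fit, x, type = "class")),
    svm = as.character(predict(object$fit, x)),
    decision_tree = {
      cls <- predict(object$fit, as.data.frame(x), type = "class")
      as.character(cls)
    })
  unname(out)
}

#' Confusion counts with malignant as the positive class
#'
#' @param predicted,truth label vectors of equal length over
#'   `benign` / `malignant`.
#' @return a `confusion_counts` list: `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c("malignant", "benign"), c("malignant", "malignant"))
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  ok <- c("benign", "malignant")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("unknown label; expected benign/malignant")
  structure(list(
    TP = sum(predicted == "malignant" & truth == "malignant"),
    TN = sum(predicted == "benign" & truth == "benign"),
    FP = sum(predicted == "malignant" & truth == "benign"),
    FN = sum(predicted == "benign" & truth == "malignant")),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)` and precision `TP/(TP+FP)`, as fractions. A metric whose
#' denominator is zero is returned as `NA` (flagged, never thrown) and is
#' excluded from downstream averages.
#'
#' @param counts a `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return a `metrics_report` list of the four fractions.
#' @examples
#' metrics(list(TP = 3, FN = 4, TN = 2, FP = 1))
#' @export
metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    div <- function(num, den) if (den > 0) num / den else NA_real_
    structure(list(
      accuracy = div(TP + TN, total),
      specificity = div(TN, TN + FP),
      sensitivity = div(TP, TP + FN),
      precision = div(TP, TP + FP)),
      class = "metrics_report")
  })
}

#' Run the full balanced-resampling classification experiment
#'
#' For each balanced subset: split into train/validation, fit the range
#' normalizer and the classifier on the training part only, and evaluate on
#' the validation part and on the fixed disjoint test set. Metrics are
#' aggregated across subsets as mean and standard deviation. Any test id
#' found in a training set aborts the run (leakage guard).
#'
#' @param features data.frame with `id`, `label` and raw feature columns
#'   for every record referenced by the subsets and the test manifest.
#' @param balanced a `balanced_subsets` object (training records only).
#' @param test_manifest data.frame with `id` and `label` of the disjoint
#'   test records.
#' @param model,params classifier choice, see [train_classifier()].
#' @param train_fraction training share within each subset.
#' @param seed master seed for splits and model fits.
#' @return a `run_summary`: list with `per_subset` (data.frame of metrics
#'   per subset and split) and `summary` (mean and sd per metric and
#'   split).
#' @export
run_experiment <- function(features, balanced, test_manifest,
                           model = "boosted_tree", params = list(),
                           train_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(balanced, "balanced_subsets"),
            all(c("id", "label") %in% names(features)),
            all(c("id", "label") %in% names(test_manifest)))
  test_ids <- test_manifest$id
  feat_ids <- features$id
  need <- unique(c(unlist(lapply(balanced$subsets, `[[`, "id")), test_ids))
  missing <- setdiff(need, feat_ids)
  if (length(missing))
    stop("no features for ", length(missing), " record(s), e.g. ",
         missing[1])

  split_seeds <- spawn_seeds(seed, length(balanced$subsets), stream = 3L)
  fit_seeds <- spawn_seeds(seed, length(balanced$subsets), stream = 4L)
  rows <- list()
  for (k in seq_along(balanced$subsets)) {
    sub <- balanced$subsets[[k]]
    if (length(intersect(sub$id, test_ids)) > 0)
      stop("leakage: test id found in training subset ", k)
    sp <- train_val_split(sub, train_fraction, split_seeds[k])
    tr <- features[match(sp$train$id, feat_ids), , drop = FALSE]
    va <- features[match(sp$validation$id, feat_ids), , drop = FALSE]
    te <- features[match(test_ids, feat_ids), , drop = FALSE]

    nrm <- normalize_features(tr)
    xcols <- names(nrm$fit)  # the model sees the normalized features only
    clf <- train_classifier(predict(nrm, tr)[, xcols, drop = FALSE],
                            tr$label, model = model,
                            params = params, seed = fit_seeds[k])
    for (split in c("validation", "test")) {
      dat <- if (split == "validation") va else te
      pred <- predict(clf, predict(nrm, dat)[, xcols, drop = FALSE])
      m <- metrics(confusion(pred, dat$label))
      rows[[length(rows) + 1]] <- data.frame(
        subset = k, split = split,
        accuracy = m$accuracy, specificity = m$specificity,
        sensitivity = m$sensitivity, precision = m$precision)
    }
  }
  per_subset <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("validation", "test"), function(s) {
    d <- per_subset[per_subset$split == s,
                    c("accuracy", "specificity", "sensitivity", "precision")]
    data.frame(split = s, metric = names(d),
               mean = vapply(d, mean, numeric(1), na.rm = TRUE),
               sd = vapply(d, sd, numeric(1), na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(per_subset = per_subset, summary = summ, model = model),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Balanced-resampling experiment (", x$model, ", ",
      length(unique(x$per_subset$subset)), " subsets)\n", sep = "")
  s <- x$summary
  s$mean <- sprintf("%.3f", s$mean); s$sd <- sprintf("%.3f", s$sd)
  print(s, row.names = FALSE)
  invisible(x)
}
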