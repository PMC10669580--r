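test_that("classifiers separate well-separated gaussian clouds", {
  gf <- gaussian_features(100, shift = 3, seed = 1)
  idx <- with(gf, sample(length(y)))
  tr <- idx[1:140]; va <- idx[141:200]
  for (mdl in c("boosted_tree", "decision_tree", "svm", "knn")) {
    clf <- train_classifier(gf$x[tr, ], gf$y[tr], model = mdl, seed = 2)
    acc <- mean(predict(clf, gf$x[va, ]) == gf$y[va])
    expect_gte(acc, 0.95)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  gf <- gaussian_features(100, shift = 3, seed = 2)
  set.seed(9)
  ysh <- sample(gf$y)
  clf <- train_classifier(gf$x[1:140, ], ysh[1:140], seed = 3)
  acc <- mean(predict(clf, gf$x[141:200, ]) == ysh[141:200])
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("training is deterministic and prediction is row-equivariant", {
  gf <- gaussian_features(60, shift = 2, seed = 4)
  c1 <- train_classifier(gf$x, gf$y, seed = 5)
  c2 <- train_classifier(gf$x, gf$y, seed = 5)
  expect_identical(predict(c1, gf$x), predict(c2, gf$x))

  perm <- sample(nrow(gf$x))
  expect_identical(predict(c1, gf$x[perm, ]), predict(c1, gf$x)[perm])
  expect_identical(predict(c1, gf$x[0, ]), character(0))

  # training accuracy at least matches validation on separable data
  idx <- 1:80
  c3 <- train_classifier(gf$x[idx, ], gf$y[idx], seed = 6)
  acc_tr <- mean(predict(c3, gf$x[idx, ]) == gf$y[idx])
  acc_va <- mean(predict(c3, gf$x[-idx, ]) == gf$y[-idx])
  expect_gte(acc_tr, acc_va - 0.01)
})

test_that("degenerate training inputs are rejected", {
  gf <- gaussian_features(10, seed = 1)
  expect_error(train_classifier(gf$x[1:10, ], gf$y[1:10]), "single class")
  expect_error(predict(train_classifier(gf$x, gf$y, seed = 1),
                       gf$x[, 1:2]), "schema")
})

test_that("confusion counts tally predictions against truth", {
  all_right <- confusion(rep(c("malignant", "benign"), c(5, 5)),
                         rep(c("malignant", "benign"), c(5, 5)))
  expect_equal(unclass(all_right)[c("TP", "TN", "FP", "FN")],
               list(TP = 5, TN = 5, FP = 0, FN = 0))
  all_mal <- confusion(rep("malignant", 10),
                       rep(c("malignant", "benign"), c(5, 5)))
  expect_equal(all_mal$TP, 5); expect_equal(all_mal$FP, 5)
  expect_equal(all_mal$TN, 0); expect_equal(all_mal$FN, 0)

  # hand tally of a printed 10-row table
  pred <- c("malignant", "benign", "benign", "malignant", "malignant",
            "benign", "malignant", "benign", "benign", "malignant")
  truth <- c("malignant", "malignant", "benign", "benign", "malignant",
             "benign", "malignant", "malignant", "benign", "benign")
  cc <- confusion(pred, truth)
  expect_equal(cc$TP, 3); expect_equal(cc$FN, 2)
  expect_equal(cc$TN, 3); expect_equal(cc$FP, 2)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 10)
  expect_error(confusion(c("bad"), c("benign")), "unknown label")
})

test_that("metric formulas and their flags are exact", {
  m <- metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(m), c(accuracy = 1, specificity = 1,
                            sensitivity = 1, precision = 1))
  m2 <- metrics(list(TP = 3, FN = 4, TN = 2, FP = 1))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$sensitivity, 3 / 7)
  expect_equal(m2$specificity, 2 / 3)
  expect_equal(m2$precision, 3 / 4)
  m3 <- metrics(list(TP = 5, FN = 0, TN = 0, FP = 0))
  expect_true(is.na(m3$specificity))
})

test_that("metrics agree with per-sample tallies on random predictions", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    pred <- sample(c("benign", "malignant"), n, replace = TRUE)
    truth <- sample(c("benign", "malignant"), n, replace = TRUE)
    cc <- confusion(pred, truth)
    m <- metrics(cc)
    expect_equal(m$accuracy, mean(pred == truth))
    prev <- cc$TP + cc$FN
    if (prev > 0 && prev < n) {
      # accuracy decomposes into prevalence-weighted sens/spec
      expect_equal(m$accuracy,
                   (prev / n) * m$sensitivity +
                   ((n - prev) / n) * m$specificity)
      expect_gte(m$accuracy, min(m$sensitivity, m$specificity))
      expect_lte(m$accuracy, max(m$sensitivity, m$specificity))
    }
  }
})

make_fake_study <- function(n_b1b = 40, n_b1m = 26, n_b3 = 20, shift = 3,
                            seed = 1) {
  rec <- toy_records(n_b1b, n_b1m, 4, 3, n_b3 * 0.8, n_b3 * 0.2)
  set.seed(seed)
  n <- nrow(rec)
  x <- matrix(rnorm(n * 4), n, 4) +
       outer(ifelse(rec$label == "malignant", shift, 0), rep(1, 4))
  colnames(x) <- paste0("f", 1:4)
  features <- cbind(rec[, c("id", "label")], as.data.frame(x))
  bal <- balance_datasets(rec, n_subsets = 3, seed = seed)
  test_manifest <- rec[rec$source == "DB3", ]
  list(features = features, bal = bal, test = test_manifest)
}

test_that("the resampling experiment recovers labels and is reproducible", {
  st <- make_fake_study()
  r1 <- suppressWarnings(
    run_experiment(st$features, st$bal, st$test, seed = 5))
  s <- r1$summary
  expect_gte(s$mean[s$split == "test" & s$metric == "accuracy"], 0.9)
  expect_true(all(s$sd >= 0, na.rm = TRUE))
  # mean lies within the per-run range
  acc <- r1$per_subset$accuracy[r1$per_subset$split == "test"]
  expect_true(mean(acc) >= min(acc) && mean(acc) <= max(acc))
  r2 <- suppressWarnings(
    run_experiment(st$features, st$bal, st$test, seed = 5))
  expect_identical(r1$per_subset, r2$per_subset)
})

test_that("the leakage guard aborts when a test id enters training", {
  st <- make_fake_study()
  poisoned <- st$bal
  poisoned$subsets[[2]] <- rbind(poisoned$subsets[[2]], st$test[1, ])
  expect_error(suppressWarnings(
    run_experiment(st$features, poisoned, st$test, seed = 5)),
    "leakage")
})
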