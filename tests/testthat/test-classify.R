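# Metric panel and the balanced repeated cross-validation protocol.

test_that("AUC equals the all-pairs concordance count, with ties at half credit", {
  expect_equal(compute_metrics(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_equal(compute_metrics(c(0.1, 0.9), c(1, 0))$auc, 0)
  expect_equal(compute_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(12)
  scores <- round(runif(50), 2)   # rounding forces ties
  labels <- rbinom(50, 1, 0.4)
  m <- compute_metrics(scores, labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (sp in pos) for (sn in neg)
    conc <- conc + (sp > sn) + 0.5 * (sp == sn)
  expect_equal(m$auc, conc / (length(pos) * length(neg)))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  base <- compute_metrics(scores, labels)$auc
  expect_equal(compute_metrics(exp(scores), labels)$auc, base)
  expect_equal(compute_metrics(2 * scores + 7, labels)$auc, base)
  expect_equal(compute_metrics(rank(scores), labels)$auc, base)
})

test_that("AUPR and weighted F1 behave on hand-checkable cases", {
  # perfect ranking: AUPR 1
  expect_equal(compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$aupr, 1)
  # single positive ranked second: AP = 1/2
  expect_equal(compute_metrics(c(0.9, 0.8, 0.2), c(0, 1, 0))$aupr, 0.5)
  # confusion and weighted F1 at the supplied hard predictions
  m <- compute_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0),
                       predicted = c(1, 1, 0, 0))
  expect_equal(unname(m$confusion), c(1, 1, 1, 1))  # tp fp tn fn
  f1_pos <- 2 * 1 / (2 * 1 + 1 + 1)
  expect_equal(m$f1_weighted, f1_pos)  # classes balanced, symmetric counts
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUPR agrees with an independent implementation when available", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.3)
  ours <- compute_metrics(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("balanced_cv trains on exactly balanced sets and partitions test folds", {
  sep <- separable_features(n_per_class = 25, gap = 0.5, seed = 21)
  cfg <- cv_config(folds = 5, repetitions = 3, model_kind = "rf",
                   grid = list(ntree = 50), seed = 5)
  res <- balanced_cv(sep$features, sep$labels, cfg)
  expect_equal(res$per_fold$n_train_pos, res$per_fold$n_train_neg)
  # each repetition's test folds partition all 50 labelled pairs
  sums <- with(res$per_fold, tapply(tp + fp + tn + fn, repetition, sum))
  expect_true(all(sums == 50))
  # every pair is scored once per repetition
  expect_true(all(res$predictions$positive_fraction >= 0 &
                  res$predictions$positive_fraction <= 1))
})

test_that("balanced_cv is bit-identical under the same seed", {
  sep <- separable_features(n_per_class = 20, gap = 1, seed = 22)
  cfg <- cv_config(folds = 4, repetitions = 2, model_kind = "rf",
                   grid = list(ntree = 50), seed = 11)
  r1 <- balanced_cv(sep$features, sep$labels, cfg)
  r2 <- balanced_cv(sep$features, sep$labels, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$importance, r2$importance)
  r3 <- balanced_cv(sep$features, sep$labels,
                    cv_config(folds = 4, repetitions = 2, model_kind = "rf",
                              grid = list(ntree = 50), seed = 12))
  expect_false(identical(r1$per_fold$auc, r3$per_fold$auc))
})

test_that("separable classes reach near-perfect AUC for all three model kinds", {
  sep <- separable_features(n_per_class = 30, gap = 4, seed = 23)
  for (kind in c("rf", "svm", "mlp")) {
    grid <- switch(kind, rf = list(ntree = 100), svm = list(cost = 1),
                   mlp = list(size = 8, decay = 1e-3))
    cfg <- cv_config(folds = 5, repetitions = 2, model_kind = kind,
                     grid = grid, seed = 3)
    res <- balanced_cv(sep$features, sep$labels, cfg)
    expect_gte(res$aggregate$mean[res$aggregate$metric == "auc"], 0.99)
  }
})

test_that("inner grid search records the chosen hyperparameters", {
  sep <- separable_features(n_per_class = 25, gap = 2, seed = 24)
  cfg <- cv_config(folds = 3, repetitions = 1, model_kind = "rf",
                   grid = list(ntree = c(50, 100), nodesize = c(1, 5)), seed = 2)
  res <- balanced_cv(sep$features, sep$labels, cfg)
  expect_true(all(grepl("ntree=(50|100),nodesize=(1|5)", res$per_fold$params)))
  expect_error(cv_config(model_kind = "rf", grid = list()), "empty")
})

test_that("random labels give chance-level AUC", {
  set.seed(31)
  X <- matrix(rnorm(120 * 10), 120)
  colnames(X) <- paste0("f", 1:10)
  rownames(X) <- paste0("m", 1:120, ":p")
  y <- setNames(rep(c(0L, 1L), 60), rownames(X))
  cfg <- cv_config(folds = 5, repetitions = 10, model_kind = "rf",
                   grid = list(ntree = 100), seed = 9)
  res <- balanced_cv(X, y, cfg)
  expect_gt(res$aggregate$mean[1], 0.4)
  expect_lt(res$aggregate$mean[1], 0.6)
})

test_that("RF feature importance finds a planted informative column", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 80
    X <- matrix(rnorm(n * 8), n)
    y <- rep(c(0L, 1L), each = n / 2)
    X[, 3] <- X[, 3] + 2.5 * y        # planted signal in column 3
    colnames(X) <- paste0("f", 1:8)
    rownames(X) <- paste0("m", 1:n, ":p")
    cfg <- cv_config(folds = 4, repetitions = 1, model_kind = "rf",
                     grid = list(ntree = 100), seed = s)
    res <- balanced_cv(X, setNames(y, rownames(X)), cfg)
    imp <- feature_importance(res)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    if (imp$feature[1] == "f3") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("feature importance is refused for non-RF results", {
  sep <- separable_features(n_per_class = 15, gap = 4, seed = 25)
  cfg <- cv_config(folds = 3, repetitions = 1, model_kind = "svm",
                   grid = list(cost = 1), seed = 1)
  res <- balanced_cv(sep$features, sep$labels, cfg)
  expect_error(feature_importance(res), "Random Forest")
})

test_that("eta-side importances dominate for concatenated features with eta-side signal", {
  featC <- default_features(mode = "concatenated")
  lab <- default_labels(mode = "concatenated")
  cfg <- cv_config(folds = 5, repetitions = 3, model_kind = "rf",
                   grid = list(ntree = 300), seed = 4)
  res <- balanced_cv(featC$pair_features, lab, cfg)
  imp <- res$importance
  eta_half <- sum(imp[grep("^eta_", names(imp))])
  fs_half <- sum(imp[grep("^fluxsum_", names(imp))])
  expect_gt(eta_half, fs_half)
})
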