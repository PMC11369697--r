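# Balanced repeated cross-validation with RF / SVM / MLP classifiers,
# inner grid-search tuning, and the evaluation metric panel.

#' Default hyperparameter grids
#'
#' Compact grids used when none is supplied: RF varies forest size, depth
#' cap and leaf size; SVM varies cost and kernel (RBF width by the usual
#' 1/p heuristic); MLP varies hidden-layer size and L2 weight decay.
#'
#' @param model_kind `"rf"`, `"svm"` or `"mlp"`.
#' @return named list of value vectors (a grid; the Cartesian product is
#'   searched).
#' @export
default_grid <- function(model_kind = c("rf", "svm", "mlp")) {
  switch(match.arg(model_kind),
    rf = list(ntree = c(100, 300), maxnodes = c(NA, 32), nodesize = c(1, 5)),
    svm = list(cost = c(0.1, 1, 10), kernel = c("radial", "linear")),
    mlp = list(size = c(16, 64), decay = c(1e-4, 1e-2)))
}

#' Cross-validation configuration
#'
#' @param folds number of outer folds (default 5).
#' @param repetitions number of repetitions of the full CV (default 100).
#' @param model_kind classifier: `"rf"`, `"svm"` or `"mlp"`.
#' @param grid hyperparameter grid (named list of value vectors); defaults
#'   to [default_grid()].  A single-combination grid skips inner tuning.
#' @param seed master seed; drives all fold splits, negative subsampling
#'   and model fits via per-repetition derived seeds.
#' @param inner_folds folds of the inner tuning CV (default 3).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(folds = 5, repetitions = 100,
                      model_kind = c("rf", "svm", "mlp"),
                      grid = NULL, seed = 1, inner_folds = 3) {
  model_kind <- match.arg(model_kind)
  if (folds < 2) stop("folds must be >= 2")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (is.null(grid)) grid <- default_grid(model_kind)
  if (!length(grid) || !all(lengths(grid) >= 1)) stop("empty hyperparameter grid")
  structure(list(folds = folds, repetitions = repetitions,
                 model_kind = model_kind, grid = grid, seed = seed,
                 inner_folds = inner_folds), class = "cv_config")
}

grid_combos <- function(grid) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# fit one classifier; returns an object usable by score_model()
fit_model <- function(kind, X, y, params) {
  y <- factor(y, levels = c(0, 1))
  if (kind == "rf") {
    maxnodes <- params$maxnodes
    if (!is.null(maxnodes) && is.na(maxnodes)) maxnodes <- NULL
    mtry <- params$mtry %||% max(floor(sqrt(ncol(X))), 1)
    fit <- randomForest::randomForest(
      x = X, y = y, ntree = params$ntree %||% 300, mtry = mtry,
      maxnodes = maxnodes, nodesize = params$nodesize %||% 1)
  } else if (kind == "svm") {
    fit <- e1071::svm(x = X, y = y, kernel = params$kernel %||% "radial",
                      cost = params$cost %||% 1, probability = FALSE)
  } else {
    capture.output(fit <- nnet::nnet(
      x = X, y = as.numeric(y) - 1, size = params$size %||% 16,
      decay = params$decay %||% 1e-4, maxit = 200, trace = FALSE,
      MaxNWts = 1e5, entropy = TRUE))
    class(fit) <- c("mpi_mlp", class(fit))
  }
  fit
}

# continuous score (larger = more positive) and hard 0/1 prediction
score_model <- function(fit, X) {
  if (inherits(fit, "randomForest")) {
    p <- predict(fit, X, type = "prob")[, "1"]
    list(score = p, predicted = as.integer(p >= 0.5))
  } else if (inherits(fit, "svm")) {
    dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
    s <- dv[, 1]
    if (grepl("^0/", colnames(dv)[1])) s <- -s  # orient toward class "1"
    list(score = s, predicted = as.integer(s > 0))
  } else {
    p <- as.numeric(predict(fit, X))
    list(score = p, predicted = as.integer(p >= 0.5))
  }
}

#' Classification metric panel
#'
#' AUC is the Mann-Whitney rank statistic (ties get half credit); AUPR is
#' average precision (the step-wise integral of the precision-recall curve);
#' weighted F1 and the confusion matrix are computed at the supplied hard
#' predictions (the classifier's native label output).
#'
#' @param scores numeric vector of classifier scores (larger = more
#'   positive).
#' @param labels 0/1 vector of true labels; both classes must be present.
#' @param predicted optional 0/1 hard predictions (default: `scores >= 0.5`).
#' @return list with `auc`, `aupr`, `f1_weighted` and `confusion`
#'   (`tp`, `fp`, `tn`, `fn`).
#' @export
compute_metrics <- function(scores, labels, predicted = NULL) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  if (is.null(predicted)) predicted <- as.integer(scores >= 0.5)

  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)

  # average precision over distinct-score thresholds, highest first
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]; l_ord <- labels[ord]
  cum_tp <- cumsum(l_ord); cum_pp <- seq_along(l_ord)
  thr <- which(!duplicated(s_ord, fromLast = TRUE))  # last index of each tie group
  prec <- cum_tp[thr] / cum_pp[thr]
  rec <- cum_tp[thr] / npos
  aupr <- sum(diff(c(0, rec)) * prec)

  tp <- sum(predicted == 1 & labels == 1); fp <- sum(predicted == 1 & labels == 0)
  tn <- sum(predicted == 0 & labels == 0); fn <- sum(predicted == 0 & labels == 1)
  f1_class <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  f1 <- (npos * f1_class(tp, fp, fn) + nneg * f1_class(tn, fn, fp)) / (npos + nneg)
  list(auc = auc, aupr = aupr, f1_weighted = f1,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

tune_params <- function(kind, X, y, grid, inner_folds) {
  combos <- grid_combos(grid)
  if (length(combos) == 1) return(combos[[1]])
  fold <- stratified_folds(y, inner_folds)
  mean_auc <- vapply(combos, function(params) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_model(kind, X[tr, , drop = FALSE], y[tr], params)
      sc <- score_model(fit, X[te, , drop = FALSE])
      compute_metrics(sc$score, y[te])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  combos[[which.max(mean_auc)]]
}

#' Balanced repeated cross-validation
#'
#' The evaluation protocol: per repetition, labelled pairs are split into
#' stratified folds; with each fold in turn held out as an (imbalanced,
#' as-is) test set, the training set is all positives of the remaining folds
#' plus an equal-size uniform random subset of their negatives, so training
#' is always exactly class-balanced.  Hyperparameters are tuned per fold by
#' an inner stratified grid-search CV on the balanced training set (skipped
#' for single-combination grids).  Metrics are averaged over folds and
#' repetitions; the whole procedure is reproducible from the master seed.
#'
#' @param features numeric matrix; rownames are pair keys.
#' @param labels a `label_set` (keys `metabolite:protein` matched against
#'   rownames) or a named 0/1 vector over a subset of rownames.
#' @param config a `cv_config`.
#' @return object of class `cv_result`: `per_fold` data.frame (one row per
#'   repetition x fold with metrics, confusion counts and chosen
#'   hyperparameters), `aggregate` (mean and sd per metric), `importance`
#'   (RF only: mean impurity importances, normalized to sum 1),
#'   `predictions` (out-of-fold mean score and positive-prediction fraction
#'   per pair), and the `config`.
#' @export
balanced_cv <- function(features, labels, config) {
  if (inherits(labels, "label_set") || is.data.frame(labels)) {
    y_all <- setNames(as.integer(labels$label), pair_ids(labels))
  } else {
    y_all <- labels
  }
  missing <- setdiff(names(y_all), rownames(features))
  if (length(missing))
    stop("labelled pairs without feature rows: ", paste(head(missing, 5), collapse = ", "))
  X <- features[names(y_all), , drop = FALSE]
  y <- as.integer(y_all)
  k <- config$folds
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop("need at least `folds` instances of each class")

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$repetitions)

  rows <- vector("list", config$repetitions * k)
  imp_sum <- NULL; imp_n <- 0L
  score_sum <- setNames(numeric(length(y)), names(y_all))
  pos_pred <- setNames(numeric(length(y)), names(y_all))
  n_tested <- setNames(integer(length(y)), names(y_all))

  for (rep in seq_len(config$repetitions)) {
    set.seed(rep_seeds[rep])
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      te <- which(fold == f)
      pool <- which(fold != f)
      pos_pool <- pool[y[pool] == 1]; neg_pool <- pool[y[pool] == 0]
      n_bal <- min(length(pos_pool), length(neg_pool))
      tr <- c(sample(pos_pool, n_bal), sample(neg_pool, n_bal))
      if (length(unique(y[te])) < 2)
        stop("a class is absent from test fold ", f, "; too few instances")
      params <- tune_params(config$model_kind, X[tr, , drop = FALSE], y[tr],
                            config$grid, config$inner_folds)
      fit <- fit_model(config$model_kind, X[tr, , drop = FALSE], y[tr], params)
      sc <- score_model(fit, X[te, , drop = FALSE])
      m <- compute_metrics(sc$score, y[te], sc$predicted)
      rows[[(rep - 1L) * k + f]] <- data.frame(
        repetition = rep, fold = f, auc = m$auc, aupr = m$aupr,
        f1_weighted = m$f1_weighted,
        tp = m$confusion["tp"], fp = m$confusion["fp"],
        tn = m$confusion["tn"], fn = m$confusion["fn"],
        n_train_pos = n_bal, n_train_neg = n_bal,
        params = paste(names(params), unlist(params), sep = "=", collapse = ","),
        row.names = NULL, stringsAsFactors = FALSE)
      score_sum[te] <- score_sum[te] + sc$score
      pos_pred[te] <- pos_pred[te] + sc$predicted
      n_tested[te] <- n_tested[te] + 1L
      if (config$model_kind == "rf") {
        imp <- randomForest::importance(fit)[, 1]
        imp_sum <- if (is.null(imp_sum)) imp else imp_sum + imp
        imp_n <- imp_n + 1L
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("auc", "aupr", "f1_weighted"),
    mean = c(mean(per_fold$auc), mean(per_fold$aupr), mean(per_fold$f1_weighted)),
    sd = c(sd(per_fold$auc), sd(per_fold$aupr), sd(per_fold$f1_weighted)))
  importance <- NULL
  if (!is.null(imp_sum)) {
    imp_mean <- imp_sum / imp_n
    tot <- sum(imp_mean)
    importance <- if (tot > 0) imp_mean / tot else
      setNames(rep(1 / length(imp_mean), length(imp_mean)), names(imp_mean))
  }
  predictions <- data.frame(
    pair = names(y_all), label = y,
    mean_score = score_sum / pmax(n_tested, 1L),
    positive_fraction = pos_pred / pmax(n_tested, 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_fold = per_fold, aggregate = agg, importance = importance,
                 predictions = predictions, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s, %d folds x %d repetitions\n",
              x$config$model_kind, x$config$folds, x$config$repetitions))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  mean %-12s %.4f (sd %.4f)\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  invisible(x)
}

#' Ranked feature importances from a Random Forest CV result
#'
#' Mean impurity-based importances across all folds and repetitions,
#' normalized to sum 1.
#'
#' @param result a `cv_result` from an RF run.
#' @return data.frame (`feature`, `importance`), sorted decreasing.
#' @export
feature_importance <- function(result) {
  if (result$config$model_kind != "rf" || is.null(result$importance))
    stop("feature importances are available for Random Forest results only")
  imp <- sort(result$importance, decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random-label control experiment
#'
#' Chance-level baseline: per repetition, pairs are given a fresh balanced
#' random labelling and one round of balanced k-fold cross-validation is
#' run; fold AUCs are pooled over repetitions.  Re-randomizing per
#' repetition makes the mean converge to 0.5 (a single fixed random
#' labelling would instead converge to a labelling-specific value, since
#' repetitions only resample folds).
#'
#' @param features numeric matrix; rownames are pair keys.
#' @param pairs data.frame (`metabolite`, `protein`) of pairs to relabel.
#' @param config a `cv_config`; `repetitions` counts labelling draws.
#' @return list with `mean_auc`, `sd_auc` and `per_fold` (repetition, fold,
#'   auc).
#' @export
random_label_control <- function(features, pairs, config) {
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$repetitions)
  rows <- vector("list", config$repetitions)
  for (rep in seq_len(config$repetitions)) {
    labels <- random_labeling(pairs, seed = rep_seeds[rep])
    cfg1 <- config
    cfg1$repetitions <- 1L
    cfg1$seed <- rep_seeds[rep]
    res <- balanced_cv(features, labels, cfg1)
    rows[[rep]] <- data.frame(repetition = rep, fold = res$per_fold$fold,
                              auc = res$per_fold$auc)
  }
  per_fold <- do.call(rbind, rows)
  list(mean_auc = mean(per_fold$auc), sd_auc = sd(per_fold$auc),
       per_fold = per_fold)
}
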