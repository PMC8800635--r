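# Classifier suite: standardization, stratified CV, KNN and comparison
# models, hyperparameter selection, and screening at the Youden cutoff.

#' Model specification
#'
#' @param kind One of `"knn"`, `"svm"`, `"gbdt"`, `"nbayes"`, `"logistic"`.
#' @param hyper Named list of hyperparameters. Recognised entries: knn -
#'   `k`, `weighting` (`"uniform"` or `"distance"`); svm - `kernel`, `cost`,
#'   `gamma`; gbdt - `n_trees`, `depth`, `learning_rate`; logistic - none
#'   (maximum-likelihood fit); nbayes - none.
#' @param rng_seed Integer seed for stochastic fitters.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(kind = c("knn", "svm", "gbdt", "nbayes", "logistic"),
                       hyper = list(), rng_seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 9L, weighting = "uniform"),
    svm = list(kernel = "radial", cost = 1, gamma = NULL),
    gbdt = list(n_trees = 100L, depth = 3L, learning_rate = 0.1),
    nbayes = list(),
    logistic = list())
  hyper <- utils::modifyList(defaults, hyper)
  if (kind == "knn" && (!is.numeric(hyper$k) || hyper$k < 1))
    hp_stop("knn 'k' must be >= 1")
  structure(list(kind = kind, hyper = hyper,
                 rng_seed = assert_count(rng_seed, "rng_seed", min = 0L)),
            class = "model_spec")
}

#' Per-feature z-score standardization fitted on selected rows
#'
#' Location and scale are estimated from `fit_rows` only, so test-fold rows
#' never influence the transform (no leakage). Zero-variance features keep
#' scale 1 with a warning.
#'
#' @param x Numeric matrix (rows = pairs, columns = features).
#' @param fit_rows Row indices used to fit the statistics (default: all).
#' @return List with `x` (the fully transformed matrix), `center`, `scale`.
#' @export
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (length(fit_rows) == 0L) hp_stop("'fit_rows' must be non-empty")
  center <- colMeans(x[fit_rows, , drop = FALSE])
  scale <- apply(x[fit_rows, , drop = FALSE], 2L, stats::sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sprintf("zero-variance feature(s) left unscaled: %s",
                    paste(colnames(x)[zero], collapse = ", ")), call. = FALSE)
    scale[zero] <- 1
  }
  list(x = sweep(sweep(x, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Apply a fitted standardization to new rows
#' @param fit Result of [standardize_features()].
#' @param x New numeric matrix with the same columns.
#' @return Transformed matrix.
#' @export
apply_standardization <- function(fit, x) {
  sweep(sweep(as.matrix(x), 2L, fit$center), 2L, fit$scale, "/")
}

#' Seeded stratified k-fold assignment
#'
#' Shuffles each class independently and deals it round-robin over folds, so
#' every fold's class ratio is within one sample of the global ratio and fold
#' sizes differ by at most one. If the rarer class has fewer members than
#' `n_folds`, the fold count is reduced with a warning.
#'
#' @param labels Vector of 0/1 class labels.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds actually used).
#' @export
stratified_kfold <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    hp_stop("stratification requires both classes to be present")
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning(sprintf("reducing folds from %d to %d (rarer class has %d members)",
                    n_folds, min_class, min_class), call. = FALSE)
    n_folds <- as.integer(min_class)
  }
  if (n_folds < 2L) hp_stop("rarer class too small for cross-validation")
  fold <- integer(length(labels))
  set.seed(seed)
  offset <- 0L
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold per class so fold sizes stay balanced
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' k-nearest-neighbour positive-class score
#'
#' Euclidean distances on (already standardized) features; the score is the
#' uniform or inverse-distance-weighted fraction of positive labels among the
#' k nearest training rows. Distance ties are broken by ascending training
#' row index.
#'
#' @param train_x Numeric training matrix.
#' @param train_y 0/1 training labels.
#' @param query_x Numeric matrix of query rows.
#' @param k Neighbourhood size (`k <= nrow(train_x)`).
#' @param weighting `"uniform"` or `"distance"`.
#' @return Numeric vector of scores in `[0, 1]`, one per query row.
#' @export
knn_score <- function(train_x, train_y, query_x, k,
                      weighting = c("uniform", "distance")) {
  weighting <- match.arg(weighting)
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  train_y <- as.numeric(train_y)
  if (k > nrow(train_x))
    hp_stop("k = %d exceeds the training set size %d", k, nrow(train_x))
  apply(query_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]  # stable: ties broken by ascending row index
    if (weighting == "uniform") {
      mean(train_y[nn])
    } else {
      w <- 1 / (d[nn] + 1e-8)
      sum(w * train_y[nn]) / sum(w)
    }
  })
}

#' Fit a model on training rows and score test rows
#'
#' Returns a real-valued score per test row with higher meaning more likely
#' effective: KNN neighbourhood vote, logistic fitted probability, Gaussian
#' naive Bayes posterior, logistic-transformed boosted score (xgboost), or
#' SVM decision value (oriented so that larger favours the positive class).
#'
#' @param spec A [model_spec()].
#' @param train_x,train_y Training matrix and 0/1 labels (both classes
#'   required).
#' @param test_x Test matrix.
#' @return Numeric score vector for the test rows.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "model_spec"))
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y)
  if (length(unique(train_y)) < 2L)
    hp_stop("training data must contain both classes")
  set.seed(spec$rng_seed)
  h <- spec$hyper
  switch(spec$kind,
    knn = knn_score(train_x, train_y, test_x, k = h$k,
                    weighting = h$weighting),
    logistic = {
      df <- data.frame(train_x); df$.y <- train_y
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = data.frame(test_x), type = "response")))
    },
    nbayes = {
      fit <- e1071::naiveBayes(train_x, factor(train_y, levels = c(0L, 1L)))
      as.numeric(stats::predict(fit, test_x, type = "raw")[, "1"])
    },
    svm = {
      y <- factor(train_y, levels = c(0L, 1L))
      gamma <- h$gamma %||% (1 / ncol(train_x))
      fit <- e1071::svm(train_x, y, kernel = h$kernel, cost = h$cost,
                        gamma = gamma, scale = FALSE)
      dv <- attr(stats::predict(fit, test_x, decision.values = TRUE),
                 "decision.values")[, 1L]
      # orient decision values so larger favours class 1
      tr <- attr(stats::predict(fit, train_x, decision.values = TRUE),
                 "decision.values")[, 1L]
      if (mean(tr[train_y == 1L]) < mean(tr[train_y == 0L])) dv <- -dv
      as.numeric(dv)
    },
    gbdt = {
      dtrain <- xgboost::xgb.DMatrix(train_x, label = train_y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = h$depth,
                      eta = h$learning_rate, nthread = 1L),
        data = dtrain, nrounds = h$n_trees, verbose = 0)
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(test_x)))
    })
}

#' Stratified cross-validation of one model
#'
#' Standardization statistics are fitted inside each training fold and
#' applied to its test fold, so no test information leaks into the transform
#' or the fit. Out-of-fold scores are pooled into a single ROC curve.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param spec A [model_spec()].
#' @param n_folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Object of class `cv_report`: `folds`, pooled out-of-fold `scores`,
#'   `roc` (staircase points), `auroc`, `cutoff`/`youden_j` from
#'   [youden_cutoff()], and the `spec`.
#' @export
cross_validate <- function(x, y, spec, n_folds = 10L, seed = 1L) {
  x <- as.matrix(x); y <- as.integer(y)
  folds <- stratified_kfold(y, n_folds, seed)
  scores <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    test <- which(folds == f); train <- which(folds != f)
    std <- standardize_features(x, fit_rows = train)
    scores[test] <- fit_predict(spec, std$x[train, , drop = FALSE], y[train],
                                std$x[test, , drop = FALSE])
  }
  rc <- roc_auroc(scores, y)
  cut <- youden_cutoff(rc$roc)
  structure(list(folds = folds, scores = scores, roc = rc$roc,
                 auroc = rc$auroc, cutoff = cut$threshold,
                 youden_j = cut$j, spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation report: %s model, %d folds\n",
              x$spec$kind, length(unique(x$folds))))
  cat(sprintf("  pooled AUROC %.3f; Youden cutoff %.3f (J = %.3f)\n",
              x$auroc, x$cutoff, x$youden_j))
  invisible(x)
}

#' Select the KNN neighbourhood size by pooled cross-validated AUROC
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param k_grid Candidate k values (default `c(3, 5, 7, 9, 11, 13)`).
#' @param n_folds Folds (default 10).
#' @param seed Fold seed (shared across the grid so folds are comparable).
#' @param weighting KNN vote weighting.
#' @return List with `best_k`, `best_report` (its `cv_report`), and
#'   `reports` (named by k).
#' @export
select_k <- function(x, y, k_grid = c(3L, 5L, 7L, 9L, 11L, 13L),
                     n_folds = 10L, seed = 1L,
                     weighting = c("uniform", "distance")) {
  if (length(k_grid) == 0L) hp_stop("'k_grid' must be non-empty")
  weighting <- match.arg(weighting)
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid < length(y)]
  reports <- lapply(k_grid, function(k)
    cross_validate(x, y, model_spec("knn", list(k = k, weighting = weighting)),
                   n_folds = n_folds, seed = seed))
  names(reports) <- k_grid
  auc <- vapply(reports, `[[`, numeric(1), "auroc")
  best <- which(auc == max(auc))[1L]  # ties: smallest k (grid is sorted)
  list(best_k = k_grid[best], best_report = reports[[best]],
       reports = reports)
}

#' Screen pairs at a score cutoff
#'
#' Retains pairs with `score >= cutoff` and summarises each herb's share
#' among the retained pairs: appearances of the herb divided by twice the
#' number of retained pairs (so the shares sum to 1).
#'
#' @param pairs Data frame with `herb_a`, `herb_b` (one row per scored pair).
#' @param scores Numeric scores aligned with `pairs`.
#' @param cutoff Retention threshold.
#' @return List of class `screen_result`: `retained` (pairs + scores),
#'   `proportions` (herb, share), and `cutoff`.
#' @export
screen_pairs <- function(pairs, scores, cutoff) {
  stopifnot(nrow(pairs) == length(scores))
  keep <- scores >= cutoff
  retained <- cbind(pairs[keep, c("herb_a", "herb_b"), drop = FALSE],
                    score = scores[keep])
  rownames(retained) <- NULL
  props <- if (nrow(retained) > 0L) {
    tab <- table(c(retained$herb_a, retained$herb_b))
    data.frame(herb = names(tab),
               share = as.numeric(tab) / (2 * nrow(retained)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(herb = character(), share = numeric(), stringsAsFactors = FALSE)
  }
  props <- props[order(-props$share, props$herb), , drop = FALSE]
  rownames(props) <- NULL
  structure(list(retained = retained, proportions = props, cutoff = cutoff),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screened pairs: %d retained at cutoff %.4f\n",
              nrow(x$retained), x$cutoff))
  invisible(x)
}
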