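test_that("standardization fits on the training rows only", {
  x <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  self <- standardize_features(x)
  expect_equal(unname(colMeans(self$x)), c(0, 0))
  expect_equal(unname(apply(self$x, 2, stats::sd)), c(1, 1))

  fit <- standardize_features(x, fit_rows = 1:2)
  expect_equal(unname(fit$center), c(1.5, 15))
  # test rows transformed with train statistics differ from a self-fit
  expect_false(isTRUE(all.equal(fit$x[3:4, ], self$x[3:4, ])))
  expect_equal(apply_standardization(fit, x[3:4, , drop = FALSE]),
               fit$x[3:4, ])

  const <- cbind(x, flat = rep(7, 4))
  expect_warning(sc <- standardize_features(const), "zero-variance")
  expect_equal(unname(sc$x[, "flat"]), rep(0, 4))
  expect_equal(unname(sc$scale["flat"]), 1)
})

test_that("stratified folds balance classes and are seeded", {
  y <- rep(c(0L, 1L), each = 10L)
  f <- stratified_kfold(y, 10L, seed = 1L)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == 0L), 1L)
    expect_equal(sum(f == k & y == 1L), 1L)
  }
  expect_identical(f, stratified_kfold(y, 10L, seed = 1L))
  expect_false(identical(f, stratified_kfold(y, 10L, seed = 2L)))

  y2 <- c(rep(0L, 30L), rep(1L, 17L))
  f2 <- stratified_kfold(y2, 10L, seed = 3L)
  expect_lte(diff(range(table(f2))), 1)

  expect_warning(f3 <- stratified_kfold(c(rep(0L, 20L), rep(1L, 4L)), 10L, 1L),
                 "reducing folds")
  expect_equal(length(unique(f3)), 4L)
  expect_error(stratified_kfold(rep(1L, 20L), 10L, 1L), "both classes")
})

test_that("KNN scores follow the neighbourhood vote", {
  train <- matrix(c(0, 1, 10), ncol = 1)
  y <- c(0, 0, 1)
  expect_equal(knn_score(train, y, matrix(1), k = 1), 0)
  expect_equal(knn_score(train, y, matrix(9), k = 3), 1 / 3)
  expect_equal(knn_score(train, rep(1, 3), matrix(5), k = 2), 1)
  expect_error(knn_score(train, y, matrix(0), k = 4), "exceeds")
  # distance weighting favours the closest neighbour
  expect_gt(knn_score(train, y, matrix(9), k = 3, weighting = "distance"),
            1 / 3)
})

test_that("KNN agrees with a brute-force neighbour search", {
  set.seed(7)
  train <- matrix(stats::rnorm(60), ncol = 3)
  y <- rep(c(0, 1), 10)
  query <- matrix(stats::rnorm(15), ncol = 3)
  for (k in c(1L, 3L, 7L)) {
    got <- knn_score(train, y, query, k)
    brute <- apply(query, 1, function(q) {
      d <- apply(train, 1, function(r) sqrt(sum((r - q)^2)))
      mean(y[order(d)[1:k]])
    })
    expect_equal(got, brute)
  }
})

test_that("all five model kinds rank separable classes correctly", {
  set.seed(11)
  n <- 30
  x <- rbind(matrix(stats::rnorm(n * 2, -2, 0.5), ncol = 2),
             matrix(stats::rnorm(n * 2, 2, 0.5), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(0L, 1L), each = n)
  for (kind in c("knn", "svm", "gbdt", "nbayes", "logistic")) {
    scores <- fit_predict(model_spec(kind), x, y, x)
    expect_equal(roc_auroc(scores, y)$auroc, 1,
                 info = kind)
  }
  expect_error(fit_predict(model_spec("knn"), x, rep(1L, nrow(x)), x),
               "both classes")
})

test_that("Gaussian naive Bayes matches the closed-form posterior", {
  x <- matrix(c(-2, 0, 1, 3), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0L, 0L, 1L, 1L)
  q <- matrix(c(-1, 0.5, 2), ncol = 1, dimnames = list(NULL, "f"))
  got <- fit_predict(model_spec("nbayes"), x, y, q)
  lik1 <- stats::dnorm(q[, 1], mean = 2, sd = stats::sd(c(1, 3)))
  lik0 <- stats::dnorm(q[, 1], mean = -1, sd = stats::sd(c(-2, 0)))
  expect_equal(got, lik1 / (lik0 + lik1), tolerance = 1e-6)
})

test_that("identical train and test with 1-NN reproduces the labels", {
  set.seed(3)
  x <- matrix(stats::rnorm(40), ncol = 2)
  y <- rep(c(0L, 1L), 10)
  scores <- fit_predict(model_spec("knn", list(k = 1L)), x, y, x)
  expect_equal(scores, as.numeric(y))
})

test_that("ROC/AUROC match the worked cases and the tie rule", {
  perfect <- roc_auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(utils::tail(perfect$roc$tpr, 1), 1)
  expect_true(all(diff(perfect$roc$fpr) >= 0))
  expect_true(all(diff(perfect$roc$tpr) >= 0))

  expect_equal(roc_auroc(c(0.8, 0.9, 0.7, 0.2), c(1, 0, 1, 0))$auroc, 0.5)
  expect_equal(roc_auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  expect_error(roc_auroc(1:4, rep(1, 4)), "one class")
})

test_that("AUROC agrees with exhaustive pair counting", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(6:40, 1)
    scores <- round(stats::runif(n), 2)  # rounding forces ties
    labels <- stats::rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auroc(scores, labels)$auroc,
                 oracle_auroc(scores, labels))
  }
})

test_that("the Youden cutoff maximizes TPR - FPR with the higher-threshold tie rule", {
  roc <- data.frame(threshold = c(Inf, 0.9, 0.6, 0.3),
                    fpr = c(0, 0, 0.5, 1), tpr = c(0, 0.5, 1, 1))
  cut <- youden_cutoff(roc)
  expect_equal(cut$j, 0.5)
  expect_equal(cut$threshold, 0.9)  # tie between 0.9 and 0.6 points

  perfect <- roc_auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(youden_cutoff(perfect$roc)$j, 1)
})

test_that("k selection maximizes pooled AUROC with deterministic ties", {
  set.seed(23)
  x <- matrix(stats::rnorm(60 * 2), ncol = 2)
  y <- rep(c(0L, 1L), 30)
  sel1 <- select_k(x, y, k_grid = 1L, n_folds = 5L, seed = 1L)
  expect_equal(sel1$best_k, 1L)
  sel2 <- select_k(x, y, k_grid = c(3L, 5L, 7L), n_folds = 5L, seed = 1L)
  sel3 <- select_k(x, y, k_grid = c(3L, 5L, 7L), n_folds = 5L, seed = 1L)
  expect_equal(sel2$best_k, sel3$best_k)
  expect_equal(sel2$best_report$auroc, sel3$best_report$auroc)
})

test_that("screening retains by cutoff and reports herb shares", {
  pairs <- data.frame(herb_a = c("A", "A", "B"), herb_b = c("B", "C", "C"))
  all_in <- screen_pairs(pairs, c(0.9, 0.8, 0.1), cutoff = 0)
  expect_equal(nrow(all_in$retained), 3L)
  expect_equal(sum(all_in$proportions$share), 1)

  scr <- screen_pairs(pairs, c(0.9, 0.8, 0.1), cutoff = 0.5)
  expect_equal(nrow(scr$retained), 2L)  # (A,B) and (A,C)
  shares <- stats::setNames(scr$proportions$share, scr$proportions$herb)
  expect_equal(shares[["A"]], 0.5)
  expect_equal(shares[["B"]], 0.25)
  expect_equal(shares[["C"]], 0.25)
})

test_that("cross-validation never leaks test rows into training transforms", {
  set.seed(31)
  x <- matrix(stats::rnorm(40 * 3), ncol = 3)
  y <- rep(c(0L, 1L), 20)
  folds <- stratified_kfold(y, 5L, seed = 1L)
  test_rows <- which(folds == 1L)
  train_rows <- which(folds != 1L)
  fit1 <- standardize_features(x, fit_rows = train_rows)
  x_perturbed <- x
  x_perturbed[test_rows[1], ] <- x_perturbed[test_rows[1], ] + 100
  fit2 <- standardize_features(x_perturbed, fit_rows = train_rows)
  expect_identical(fit1$center, fit2$center)
  expect_identical(fit1$scale, fit2$scale)
  expect_identical(fit1$x[train_rows, ], fit2$x[train_rows, ])
})
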