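test_that("stratified split reproduces the cohort arithmetic", {
  labels <- setNames(rep(c("G1", "G2", "G3"), c(50, 45, 46)),
                     sprintf("S%03d", 1:141))
  p <- stratified_split(labels, 0.8, seed = 4)
  expect_length(p$train_ids, 113)
  expect_length(p$test_ids, 28)
  expect_equal(as.numeric(p$train_counts[c("G1", "G2", "G3")]), c(40, 36, 37))
  expect_equal(as.numeric(p$test_counts[c("G1", "G2", "G3")]), c(10, 9, 9))
  expect_length(intersect(p$train_ids, p$test_ids), 0)
  expect_setequal(c(p$train_ids, p$test_ids), names(labels))

  # (10,10) at 0.7 -> (7,7)/(3,3)
  l2 <- setNames(rep(c("A", "B"), each = 10), paste0("x", 1:20))
  p2 <- stratified_split(l2, 0.7, seed = 1)
  expect_equal(as.numeric(p2$train_counts), c(7, 7))
  expect_equal(as.numeric(p2$test_counts), c(3, 3))

  # degenerate fractions guarded
  expect_error(stratified_split(l2, 1.0, seed = 1), "empty test")
  expect_error(stratified_split(setNames(c("A", "B"), c("s1", "s2")), 0.8),
               ">= 2")
})

test_that("CV folds are deterministic, stratified to within one sample", {
  y <- rep(c(0, 1), c(40, 73))
  f1 <- fitTriage:::stratified_folds(y, 10, seed = 3)
  f2 <- fitTriage:::stratified_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:10) {
    expect_lte(abs(sum(y[f1 == k] == 1) - 7.3), 1)
    expect_lte(abs(sum(y[f1 == k] == 0) - 4.0), 1)
  }
})

test_that("tuning handles degenerate grids, nulls, and separable panels", {
  set.seed(50)
  n <- 80
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("F", 1:5)))
  # degenerate single-point grid
  tf <- tune_and_fit(x, y, "penalized_logistic",
                     grid = data.frame(alpha = 0, lambda = 0.06),
                     cv_folds = 5, cv_repeats = 1, seed = 2)
  expect_equal(nrow(tf$cv_result$grid), 1)
  expect_equal(tf$model$hyperparameters$lambda, 0.06)

  # label-permuted data: CV AUROC near chance
  tf0 <- tune_and_fit(x, y, "penalized_logistic",
                      grid = data.frame(alpha = 0,
                                        lambda = c(0.01, 0.1)),
                      cv_folds = 5, cv_repeats = 2, seed = 3)
  expect_gte(tf0$cv_result$cv_mean_auroc, 0.35)
  expect_lte(tf0$cv_result$cv_mean_auroc, 0.65)

  # linearly separable panel: CV AUROC >= 0.95
  xs <- x
  xs[, 1] <- y * 4 + rnorm(n, sd = 0.3)
  tfs <- tune_and_fit(xs, y, "penalized_logistic",
                      grid = data.frame(alpha = 0, lambda = c(0.01, 0.06)),
                      cv_folds = 10, cv_repeats = 3, seed = 4)
  expect_gte(tfs$cv_result$cv_mean_auroc, 0.95)
  expect_error(tune_and_fit(x, y, "penalized_logistic",
                            grid = data.frame()[0, ]), "non-empty")
})

test_that("all six classifier wrappers satisfy the probability contract", {
  set.seed(51)
  n <- 60
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("F", 1:4)))
  x[, 1] <- y * 3 + rnorm(n, sd = 0.5)
  hp <- list(rf = list(num_trees = 100, mtry = 2),
             xgb = list(nrounds = 30), knn = list(k = 5),
             penalized_logistic = list(alpha = 0, lambda = 0.06),
             svm = list(degree = 2, cost = 1), naive_bayes = list())
  for (alg in names(hp)) {
    fit <- fit_classifier(x, y, alg, hp[[alg]], seed = 9)
    p <- fit$predict_prob(x)
    expect_length(p, n)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auroc_rank(p, y), 0.9)      # informative feature is learnable
  }
  expect_error(fit_classifier(x, y, "perceptron"), "unknown")
})

test_that("overfit gap reproduces the printed worked examples", {
  g <- overfit_gap(0.956, 0.921)
  expect_equal(g$delta_auroc, 0.035)
  expect_equal(round(g$percent_of_cv, 1), 3.8)
  expect_true(g$stable)

  g2 <- overfit_gap(1.000, 0.904)
  expect_equal(g2$delta_auroc, 0.096)
  expect_equal(round(g2$percent_of_cv, 1), 10.6)
  expect_false(g2$stable)

  g3 <- overfit_gap(0.8, 0.8)
  expect_equal(g3$delta_auroc, 0)
  expect_equal(g3$percent_of_cv, 0)

  # stability flag withheld at or below chance
  expect_true(is.na(overfit_gap(0.6, 0.5)$stable))
})

test_that("learning curves saturate on separable data and stay flat on nulls", {
  set.seed(52)
  n <- 100
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  x[, 1] <- ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.2)
  lc <- hybrid_learning_curve(x, y, "penalized_logistic",
                              list(alpha = 0, lambda = 0.01),
                              fractions = c(0.3, 0.6, 0.9),
                              repeats = 5, seed = 7)
  expect_true(all(lc$mean_auroc >= 0.98))
  expect_true(all(lc$sem_auroc >= 0))

  xnull <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  lc0 <- hybrid_learning_curve(xnull, y, "penalized_logistic",
                               list(alpha = 0, lambda = 0.06),
                               fractions = c(0.3, 0.6, 0.9),
                               repeats = 8, seed = 8)
  expect_true(all(abs(lc0$mean_auroc - 0.5) <= 0.12))

  # repeats = 1, single fraction: one stratified hold-out row
  lc1 <- hybrid_learning_curve(x, y, "penalized_logistic",
                               list(alpha = 0, lambda = 0.01),
                               fractions = 0.5, repeats = 1, seed = 9)
  expect_equal(nrow(lc1), 1)
  expect_equal(lc1$repeats_used, 1)
})
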