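#' Stratified train/test split with round-half-up class counts
#'
#' Per class, the train count is round-half-up of `train_fraction * n`;
#' sampling within class is uniform given the seed; remaining samples go to
#' the test side. With class sizes (50, 45, 46) and fraction 0.8 this
#' reproduces a 113/28 split with test counts (10, 9, 9).
#'
#' @param labels factor/character class labels (can be the 3-level diagnostic
#'   group to stratify G1/G2/G3 jointly).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return A `partition`: `train_ids`, `test_ids` (indices or names),
#'   per-class counts, `seed`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  ids <- names(labels) %||% seq_along(labels)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs >= 2 samples")
  set.seed(seed)
  train_ids <- character(0)
  for (cl in names(tab)) {
    n_cl <- tab[[cl]]
    n_train <- round_half_up(train_fraction * n_cl)
    if (n_train < 1L) stop(sprintf("class %s would get 0 training samples", cl))
    if (n_train >= n_cl) {
      stop(sprintf("class %s would get an empty test side", cl))
    }
    members <- ids[labels == cl]
    train_ids <- c(train_ids, sample(members, n_train))
  }
  train_ids <- as.character(train_ids)
  test_ids <- setdiff(as.character(ids), train_ids)
  structure(list(
    train_ids = train_ids, test_ids = test_ids,
    train_counts = table(labels[match(train_ids, ids)]),
    test_counts = table(labels[match(test_ids, ids)]),
    seed = seed
  ), class = "partition")
}

round_half_up <- function(x) floor(x + 0.5)

# Stratified fold assignment: per class, shuffled round-robin; per-fold class
# proportions differ from global by at most one sample.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
  }
  folds
}

#' Fit one classification algorithm with fixed hyperparameters
#'
#' Uniform probability-predictor contract over six algorithms: `rf` (ranger),
#' `xgb` (xgboost), `knn` (class::knn with probability votes), `
#' penalized_logistic` (glmnet, mixing alpha and penalty lambda), `svm`
#' (e1071, polynomial kernel, probability model) and `naive_bayes` (e1071).
#'
#' @param x samples x features matrix.
#' @param y binary labels (logical or 0/1; 1 = case).
#' @param algorithm_id algorithm name.
#' @param hyperparameters named list (see default grids in
#'   [default_grids()]).
#' @param seed integer seed.
#' @return A `fitted_classifier` with a `predict_prob(newx)` closure
#'   returning case probabilities.
#' @export
fit_classifier <- function(x, y, algorithm_id, hyperparameters = list(),
                           seed = 1L) {
  y <- as.integer(as.logical(y))
  hp <- hyperparameters
  set.seed(seed)
  predict_prob <- switch(
    algorithm_id,
    penalized_logistic = {
      lam <- hp$lambda %||% 0.06
      # fit along a decreasing path ending at the target penalty (single
      # small-lambda fits converge poorly); predict at the target
      path <- sort(unique(c(exp(seq(log(max(1, lam * 10)), log(lam),
                                    length.out = 15)), lam)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(x, y, family = "binomial",
                            alpha = hp$alpha %||% 0,
                            lambda = path, standardize = FALSE)
      idx <- which.min(abs(fit$lambda - lam))
      function(newx) {
        stats::predict(fit, newx, type = "response")[, idx]
      }
    },
    rf = {
      fit <- ranger::ranger(
        x = as.data.frame(x), y = factor(y, levels = 0:1),
        num.trees = hp$num_trees %||% 500L, mtry = hp$mtry %||% NULL,
        min.node.size = hp$min_node_size %||% NULL,
        probability = TRUE, seed = seed, num.threads = 1L
      )
      function(newx) {
        stats::predict(fit, as.data.frame(newx),
                       num.threads = 1L)$predictions[, "1"]
      }
    },
    xgb = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(
          objective = "binary:logistic",
          max_depth = hp$max_depth %||% 3L, eta = hp$eta %||% 0.1,
          subsample = hp$subsample %||% 1, nthread = 1L,
          seed = seed
        ),
        data = dtr, nrounds = hp$nrounds %||% 100L, verbose = 0
      )
      function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx))
    },
    knn = {
      k <- hp$k %||% 5L
      train_x <- x; train_y <- factor(y, levels = 0:1)
      function(newx) {
        pr <- class::knn(train_x, newx, train_y, k = k, prob = TRUE, use.all = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }
    },
    svm = {
      fit <- e1071::svm(
        x, factor(y, levels = 0:1), kernel = hp$kernel %||% "polynomial",
        degree = hp$degree %||% 2L, cost = hp$cost %||% 1,
        gamma = hp$gamma %||% (1 / ncol(x)), coef0 = hp$coef0 %||% 1,
        probability = TRUE, scale = FALSE
      )
      function(newx) {
        attr(stats::predict(fit, newx, probability = TRUE),
             "probabilities")[, "1"]
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(as.data.frame(x), factor(y, levels = 0:1),
                               laplace = hp$laplace %||% 0)
      function(newx) {
        stats::predict(fit, as.data.frame(newx), type = "raw")[, "1"]
      }
    },
    stop(sprintf("unknown algorithm_id '%s'", algorithm_id))
  )
  structure(list(
    algorithm_id = algorithm_id, hyperparameters = hp, seed = seed,
    predict_prob = predict_prob, n_features = ncol(x)
  ), class = "fitted_classifier")
}

#' Default hyperparameter search grids
#'
#' Conventional ranges per algorithm (the study's own grids live outside the
#' main text, so these defaults are non-authoritative and overridable). The
#' penalized-logistic grid crosses mixing alpha in \{0, 0.25, 0.5, 0.75, 1\}
#' with 20 log-spaced penalties in \[1e-4, 1\].
#'
#' @param algorithm_id algorithm name.
#' @return A data frame, one row per grid point.
#' @export
default_grids <- function(algorithm_id) {
  switch(
    algorithm_id,
    penalized_logistic = expand.grid(
      alpha = c(0, 0.25, 0.5, 0.75, 1),
      lambda = exp(seq(log(1e-4), log(1), length.out = 20))
    ),
    rf = expand.grid(mtry = c(2L, 4L, 8L), min_node_size = c(1L, 5L)),
    xgb = expand.grid(nrounds = c(50L, 150L), max_depth = c(2L, 4L),
                      eta = c(0.1, 0.3)),
    knn = data.frame(k = c(3L, 5L, 7L, 9L, 11L)),
    svm = expand.grid(degree = c(1L, 2L, 3L), cost = c(0.25, 1, 4)),
    naive_bayes = data.frame(laplace = c(0, 0.5, 1)),
    stop(sprintf("unknown algorithm_id '%s'", algorithm_id))
  )
}

#' Tune hyperparameters by repeated stratified CV and fit the final model
#'
#' Evaluates every grid point with stratified 10-fold cross-validation
#' repeated 3 times, scoring by AUROC (the a-priori optimization metric),
#' then refits the best setting on the full training data. Ties are broken
#' toward stronger regularization / the simpler setting (later grid rows are
#' assumed at least as regularized; the penalized-logistic grid orders
#' penalties increasing, and the first maximum among ties after reverse scan
#' wins).
#'
#' @param x training samples x features.
#' @param y binary labels.
#' @param algorithm_id algorithm name.
#' @param grid data frame of settings (default [default_grids()]).
#' @param cv_folds,cv_repeats CV design (defaults 10 and 3).
#' @param seed integer seed (fold assignment and fits).
#' @return A list with `model` (a `fitted_classifier`) and `cv_result`
#'   (grid with mean/SD AUROC, chosen row, per-fold AUROCs of the chosen
#'   setting).
#' @export
tune_and_fit <- function(x, y, algorithm_id, grid = NULL, cv_folds = 10L,
                         cv_repeats = 3L, seed = 1L) {
  y <- as.integer(as.logical(y))
  if (is.null(grid)) grid <- default_grids(algorithm_id)
  if (nrow(grid) == 0L) stop("grid must be non-empty")
  fold_sets <- lapply(seq_len(cv_repeats), function(r) {
    stratified_folds(y, cv_folds, seed = seed * 100L + r)
  })
  n_settings <- nrow(grid)
  fold_auc <- matrix(NA_real_, n_settings, cv_folds * cv_repeats)
  col <- 0L
  for (r in seq_len(cv_repeats)) {
    folds <- fold_sets[[r]]
    for (f in seq_len(cv_folds)) {
      col <- col + 1L
      te <- folds == f
      if (length(unique(y[!te])) < 2L || length(unique(y[te])) < 2L) next
      xtr <- x[!te, , drop = FALSE]; ytr <- y[!te]
      xte <- x[te, , drop = FALSE]
      for (g in seq_len(n_settings)) {
        hp <- as.list(grid[g, , drop = FALSE])
        fit <- fit_classifier(xtr, ytr, algorithm_id, hp,
                              seed = seed + 7L * g)
        p <- fit$predict_prob(xte)
        fold_auc[g, col] <- auroc_rank(p, y[te])
      }
    }
  }
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  sd_auc <- apply(fold_auc, 1, stats::sd, na.rm = TRUE)
  # ties toward the later (more regularized / simpler by convention) row
  best <- max(which(mean_auc >= max(mean_auc) - 1e-12))
  hp_best <- as.list(grid[best, , drop = FALSE])
  model <- fit_classifier(x, y, algorithm_id, hp_best, seed = seed)
  cv_result <- list(
    grid = cbind(grid, mean_auroc = mean_auc, sd_auroc = sd_auc),
    chosen = hp_best,
    chosen_index = best,
    cv_mean_auroc = mean_auc[best],
    cv_sd_auroc = sd_auc[best],
    fold_aurocs = fold_auc[best, ]
  )
  list(model = model, cv_result = cv_result)
}

#' Overfitting gap between training and cross-validated AUROC
#'
#' Delta = training AUROC - CV mean AUROC; percent = 100 * Delta / CV mean.
#' A configurable threshold (default 5%) marks stable generalization; the
#' stability flag is withheld when the CV mean is at or below chance.
#'
#' @param train_auroc AUROC of the fitted model on its own training data.
#' @param cv_mean_auroc mean cross-validated AUROC.
#' @param flag_threshold_pct stability threshold in percent (default 5).
#' @return A list with `delta_auroc`, `percent_of_cv`, `stable` (logical or
#'   NA when withheld).
#' @export
overfit_gap <- function(train_auroc, cv_mean_auroc, flag_threshold_pct = 5) {
  delta <- train_auroc - cv_mean_auroc
  pct <- 100 * delta / cv_mean_auroc
  stable <- if (cv_mean_auroc <= 0.5) NA else pct < flag_threshold_pct
  list(delta_auroc = delta, percent_of_cv = pct, stable = stable)
}

#' Hybrid learning curve (repeated stratified hold-out)
#'
#' For each training fraction f and repeat: draw a stratified subsample of
#' size f of the supplied training set, fit with the fixed hyperparameters
#' (no re-tuning), and evaluate AUROC on the complementary hold-out; report
#' mean and SEM per fraction. Fractions leaving either side single-class are
#' skipped with a warning.
#'
#' @param x training samples x features.
#' @param y binary labels.
#' @param algorithm_id algorithm name.
#' @param hyperparameters fixed hyperparameters from tuning.
#' @param fractions training fractions (default 0.1..0.9).
#' @param repeats subsampling repeats per fraction (default 10).
#' @param seed integer seed.
#' @return A data frame with `fraction`, `mean_auroc`, `sem_auroc`,
#'   `repeats_used`.
#' @export
hybrid_learning_curve <- function(x, y, algorithm_id, hyperparameters,
                                  fractions = seq(0.1, 0.9, by = 0.1),
                                  repeats = 10L, seed = 1L) {
  y <- as.integer(as.logical(y))
  rows <- list()
  for (f in fractions) {
    aucs <- numeric(0)
    for (r in seq_len(repeats)) {
      sp <- tryCatch(
        stratified_split(stats::setNames(y, seq_along(y)), f,
                         seed = seed * 1000L + round(f * 100) * 10L + r),
        error = function(e) NULL
      )
      if (is.null(sp)) next
      tr <- as.integer(sp$train_ids); te <- as.integer(sp$test_ids)
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) next
      fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], algorithm_id,
                            hyperparameters, seed = seed + r)
      aucs <- c(aucs, auroc_rank(fit$predict_prob(x[te, , drop = FALSE]),
                                 y[te]))
    }
    if (length(aucs) == 0L) {
      warning(sprintf("fraction %.2f skipped: single-class side", f),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, mean_auroc = mean(aucs),
      sem_auroc = stats::sd(aucs) / sqrt(length(aucs)),
      repeats_used = length(aucs)
    )
  }
  do.call(rbind, rows)
}
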