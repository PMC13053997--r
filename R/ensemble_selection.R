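#' Run one feature-selection algorithm with one seed
#'
#' Uniform contract over five supervised selectors: every algorithm returns a
#' full importance vector and a deterministic ranking (ties broken by score,
#' then feature id). Algorithms:
#' \describe{
#'   \item{rf}{random forest (ranger), permutation importance by default
#'     (`options$importance = "impurity"` switches).}
#'   \item{rrf}{regularized random forest: ranger with a regularization
#'     factor < 1 penalizing re-use of features across splits.}
#'   \item{boruta}{shadow-feature permutation test: each iteration appends
#'     permuted copies of all features, fits a forest and counts "hits"
#'     (importance above the best shadow); features are confirmed/rejected by
#'     a binomial test, iterating up to `options$max_iter` (default 100,
#'     early-stopped); score = hit fraction, confirmed features ranked before
#'     tentative, then rejected (`options$confirmed_only` keeps only
#'     confirmed ones with positive score).}
#'   \item{svm_rfe}{recursive feature elimination with a radial-basis SVM;
#'     the per-feature elimination criterion is the change in the fitted
#'     margin term when the feature is dropped from the RBF kernel (the
#'     kernel factorizes over features, so this is exact); 20% of features
#'     are dropped per step, one-by-one below 40.}
#'   \item{lasso}{L1 logistic path (glmnet); score = |coefficient| at the
#'     cross-validation-chosen penalty (`options$bootstrap = TRUE` fits on a
#'     bootstrap resample, the "modified models" variant).}
#' }
#'
#' @param x numeric matrix, samples x features (training partition only).
#' @param y binary labels (logical or 0/1).
#' @param algorithm_id one of `"rf"`, `"rrf"`, `"boruta"`, `"svm_rfe"`,
#'   `"lasso"`.
#' @param seed integer seed.
#' @param options named list of per-algorithm options (see Details).
#' @return A `ranked_list`: `algorithm_id`, `seed`, `scores` (named), and
#'   `ranking` (feature ids by decreasing score).
#' @export
run_selector <- function(x, y, algorithm_id, seed = 1L, options = list()) {
  y <- as.integer(as.logical(y))
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  scores <- switch(
    algorithm_id,
    rf = selector_rf(x, y, seed, options, regularized = FALSE),
    rrf = selector_rf(x, y, seed, options, regularized = TRUE),
    boruta = selector_boruta(x, y, seed, options),
    svm_rfe = selector_svm_rfe(x, y, seed, options),
    lasso = selector_lasso(x, y, seed, options),
    stop(sprintf("unknown algorithm_id '%s'", algorithm_id))
  )
  ord <- order(-scores, colnames(x))
  structure(list(
    algorithm_id = algorithm_id, seed = seed,
    scores = stats::setNames(scores, colnames(x)),
    ranking = colnames(x)[ord]
  ), class = "ranked_list")
}

selector_rf <- function(x, y, seed, options, regularized) {
  imp_type <- options$importance %||% "permutation"
  num_trees <- options$num_trees %||% 500L
  if (isTRUE(options$bootstrap)) {
    set.seed(seed)
    idx <- sample.int(nrow(x), replace = TRUE)
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  args <- list(
    x = as.data.frame(x), y = factor(y), num.trees = num_trees,
    importance = imp_type, seed = seed, num.threads = 1L,
    respect.unordered.factors = "order"
  )
  if (regularized) {
    args$regularization.factor <- options$regularization_factor %||% 0.8
    args$regularization.usedepth <- TRUE
  }
  fit <- do.call(ranger::ranger, args)
  imp <- fit$variable.importance
  imp[colnames(x)]
}

selector_boruta <- function(x, y, seed, options) {
  max_iter <- options$max_iter %||% 100L
  num_trees <- options$num_trees %||% 100L
  alpha <- options$alpha %||% 0.01
  p <- ncol(x)
  set.seed(seed)
  status <- rep("tentative", p)        # tentative / confirmed / rejected
  names(status) <- colnames(x)
  hits <- stats::setNames(integer(p), colnames(x))
  n_iter <- 0L
  active <- colnames(x)
  while (n_iter < max_iter && length(active) > 0) {
    n_iter <- n_iter + 1L
    xa <- x[, active, drop = FALSE]
    shadow <- apply(xa, 2, sample)
    colnames(shadow) <- paste0("shadow_", active)
    fit <- ranger::ranger(
      x = as.data.frame(cbind(xa, shadow)), y = factor(y),
      num.trees = num_trees, importance = "impurity",
      seed = seed * 1000L + n_iter, num.threads = 1L
    )
    imp <- fit$variable.importance
    shadow_max <- max(imp[paste0("shadow_", active)])
    hit <- imp[active] > shadow_max
    hits[active[hit]] <- hits[active[hit]] + 1L
    # two-sided binomial decisions on accumulated hits over n_iter trials
    for (f in active) {
      p_hi <- stats::pbinom(hits[f] - 1L, n_iter, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], n_iter, 0.5)
      if (p_hi < alpha / 2) status[f] <- "confirmed"
      else if (p_lo < alpha / 2) status[f] <- "rejected"
    }
    active <- names(status)[status == "tentative"]
  }
  frac <- hits / pmax(n_iter, 1L)
  # confirmed ranked before tentative before rejected, by hit fraction
  tier <- c(confirmed = 2, tentative = 1, rejected = 0)[status]
  if (isTRUE(options$confirmed_only)) {
    score <- ifelse(status == "confirmed", frac, 0)
  } else {
    score <- tier + frac                # tier offsets keep strata ordered
  }
  unname_to(score, colnames(x))
}

unname_to <- function(x, ids) stats::setNames(as.numeric(x[ids]), ids)

selector_svm_rfe <- function(x, y, seed, options) {
  cost <- options$cost %||% 1
  set.seed(seed)
  if (isTRUE(options$bootstrap)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    # keep both classes
    if (length(unique(y[idx])) < 2L) idx <- seq_len(nrow(x))
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  p <- ncol(x)
  remaining <- colnames(x)
  elim_order <- character(0)            # first eliminated = least important
  while (length(remaining) > 1L) {
    xs <- x[, remaining, drop = FALSE]
    gamma <- 1 / ncol(xs)
    fit <- e1071::svm(xs, factor(y), kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE)
    crit <- rfe_criterion(xs, fit, gamma)
    n_drop <- if (length(remaining) > 40L) {
      max(1L, floor(0.2 * length(remaining)))
    } else 1L
    drop_f <- remaining[order(crit, remaining)][seq_len(n_drop)]
    elim_order <- c(elim_order, drop_f)
    remaining <- setdiff(remaining, drop_f)
  }
  elim_order <- c(elim_order, remaining)
  # score = elimination position (survivors highest)
  stats::setNames(seq_len(p), elim_order)[colnames(x)]
}

# Margin-based elimination criterion for an RBF SVM: the RBF kernel
# factorizes over features, so the kernel without feature j is
# K * exp(gamma * d_j^2); the criterion is the signed change in the fitted
# margin term alpha' K alpha when j is dropped (alpha held fixed). Features
# whose removal lowers the term carry discriminative structure and get large
# positive values; noise features score negative. Eliminate lowest first.
rfe_criterion <- function(xs, fit, gamma) {
  sv <- fit$SV
  a <- fit$coefs                       # y_i * alpha_i on support vectors
  d2 <- as.matrix(stats::dist(sv))^2
  K <- exp(-gamma * d2)
  base <- drop(t(a) %*% K %*% a)
  vapply(seq_len(ncol(sv)), function(j) {
    dj2 <- outer(sv[, j], sv[, j], "-")^2
    Kj <- K * exp(gamma * dj2)
    base - drop(t(a) %*% Kj %*% a)
  }, numeric(1))
}

selector_lasso <- function(x, y, seed, options) {
  set.seed(seed)
  if (isTRUE(options$bootstrap)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    if (length(unique(y[idx])) < 2L) idx <- seq_len(nrow(x))
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          nfolds = options$nfolds %||% 10L,
                          standardize = FALSE)
  b <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  stats::setNames(abs(b), colnames(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Borda-count rank aggregation
#'
#' Each list awards `K - rank + 1` points to its top-K features (0 beyond K);
#' Borda scores are the point sums across lists. Ties are broken by mean rank
#' across lists, then lexicographic feature id, making the consensus
#' deterministic. Accepts `ranked_list` objects or plain character rankings,
#' including per-algorithm consensus rankings for the second aggregation
#' level.
#'
#' @param ranked_lists list of `ranked_list` objects or character vectors.
#' @param K truncation depth (default 25).
#' @param features optional feature universe; features never ranked get
#'   score 0. Defaults to the union of the rankings.
#' @return A `consensus_ranking`: `borda_scores` (all features), `top_k`
#'   (ordered), `K`.
#' @export
borda_aggregate <- function(ranked_lists, K = 25L, features = NULL) {
  if (K < 1L) stop("K must be >= 1")
  rankings <- lapply(ranked_lists, function(rl) {
    if (inherits(rl, "ranked_list")) rl$ranking
    else if (inherits(rl, "consensus_ranking")) rl$top_k
    else as.character(rl)
  })
  features <- sort(unique(c(features, unlist(rankings))))
  pts <- stats::setNames(numeric(length(features)), features)
  rank_sum <- stats::setNames(numeric(length(features)), features)
  for (r in rankings) {
    kk <- min(K, length(r))
    top <- r[seq_len(kk)]
    pts[top] <- pts[top] + (kk:1)
    # features beyond K (or absent) get rank K+1 for tie-breaking
    rk <- stats::setNames(rep(K + 1, length(features)), features)
    rk[top] <- seq_len(kk)
    rank_sum <- rank_sum + rk
  }
  ord <- order(-pts, rank_sum, features)
  structure(list(
    borda_scores = pts[ord],
    top_k = features[ord][seq_len(min(K, length(features)))],
    K = K
  ), class = "consensus_ranking")
}

#' Rank-stability curve across runs
#'
#' For each k in `k_min:k_max`, agreement between runs is the mean over all
#' run pairs of the Spearman rank correlation computed on the union of the
#' two runs' top-k features; a feature absent from one run's top-k is
#' assigned rank k+1 there (tied).
#'
#' @param ranked_lists at least two rankings from the same algorithm.
#' @param k_min,k_max range of panel depths (defaults 3 and 25).
#' @return A data frame with `k` and `mean_pairwise_spearman`.
#' @export
stability_curve <- function(ranked_lists, k_min = 3L, k_max = 25L) {
  rankings <- lapply(ranked_lists, function(rl) {
    if (inherits(rl, "ranked_list")) rl$ranking else as.character(rl)
  })
  if (length(rankings) < 2L) stop("need >= 2 ranked lists")
  n_feat <- min(lengths(rankings))
  if (k_max > n_feat) stop("k_max exceeds feature count")
  ks <- k_min:k_max
  mean_rho <- vapply(ks, function(k) {
    tops <- lapply(rankings, utils::head, k)
    pairs <- utils::combn(length(rankings), 2)
    rho <- apply(pairs, 2, function(ij) {
      a <- tops[[ij[1]]]; b <- tops[[ij[2]]]
      u <- union(a, b)
      ra <- stats::setNames(rep(k + 1, length(u)), u); ra[a] <- seq_along(a)
      rb <- stats::setNames(rep(k + 1, length(u)), u); rb[b] <- seq_along(b)
      suppressWarnings(stats::cor(ra, rb[names(ra)], method = "spearman"))
    })
    mean(rho, na.rm = TRUE)
  }, numeric(1))
  data.frame(k = ks, mean_pairwise_spearman = mean_rho)
}

#' Overlap table between consensus lists
#'
#' Pairwise intersection counts and the size of the common intersection
#' (Venn cardinalities) of two or more consensus top-K lists.
#'
#' @param ... two or more `consensus_ranking` objects or character vectors.
#' @return A list with `pairwise` (matrix of intersection counts) and
#'   `common` (size of the overall intersection).
#' @export
consensus_overlap <- function(...) {
  lists <- lapply(list(...), function(l) {
    if (inherits(l, "consensus_ranking")) l$top_k else as.character(l)
  })
  if (length(lists) < 2L) stop("need >= 2 consensus lists")
  nm <- names(lists)
  if (is.null(nm) || any(nm == "")) nm <- paste0("list", seq_along(lists))
  n <- length(lists)
  pw <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pw[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  }
  list(pairwise = pw, common = length(Reduce(intersect, lists)))
}

#' Multi-seed, multi-algorithm consensus feature selection
#'
#' Runs each algorithm `runs` times with seeds `seed_base + 1:runs`,
#' aggregates each algorithm's runs into a per-algorithm Borda consensus,
#' then aggregates the per-algorithm top-K lists into the final consensus —
#' the two-level Borda scheme. Also returns per-algorithm stability curves.
#'
#' @param x samples x features matrix (training partition only).
#' @param y binary labels.
#' @param algorithms character vector of selector ids.
#' @param runs seeds per algorithm (default 50).
#' @param K consensus depth (default 25).
#' @param seed_base offset for per-run seeds.
#' @param options per-algorithm options, named by algorithm id.
#' @param stability compute stability curves (default TRUE).
#' @return A list with `consensus` (final `consensus_ranking`),
#'   `per_algorithm` (consensus per algorithm), `runs` (all ranked lists),
#'   and `stability` (data frame per algorithm).
#' @export
run_ensemble_selection <- function(x, y,
                                   algorithms = c("rf", "rrf", "boruta",
                                                  "svm_rfe", "lasso"),
                                   runs = 50L, K = 25L, seed_base = 1000L,
                                   options = list(), stability = TRUE) {
  all_runs <- list()
  per_alg <- list()
  stab <- list()
  for (alg in algorithms) {
    rls <- lapply(seq_len(runs), function(r) {
      run_selector(x, y, alg, seed = seed_base + r,
                   options = options[[alg]] %||% list())
    })
    all_runs[[alg]] <- rls
    per_alg[[alg]] <- borda_aggregate(rls, K = K)
    if (stability && runs >= 2L) {
      stab[[alg]] <- stability_curve(rls, k_min = min(3L, K), k_max = K)
    }
  }
  list(
    consensus = borda_aggregate(per_alg, K = K),
    per_algorithm = per_alg,
    runs = all_runs,
    stability = stab
  )
}
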