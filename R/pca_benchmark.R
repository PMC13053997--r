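#' Monte-Carlo parallel analysis for PC retention
#'
#' For each PC index j, the observed eigenvalue is compared with the chosen
#' percentile (default 95th) of the j-th eigenvalues of `n_sim` standard-normal
#' matrices of identical shape; the leading run of PCs exceeding their
#' thresholds is retained. Input rows are samples, columns z-scored features,
#' so covariance and correlation eigenvalues coincide.
#'
#' @param x numeric matrix, samples x features (z-scored features).
#' @param n_sim number of simulated noise matrices (default 1000).
#' @param percentile eigenvalue percentile used as threshold (default 0.95).
#' @param seed integer seed for the simulations.
#' @return A list with `n_retained`, `eigenvalues`, `thresholds`.
#' @export
parallel_analysis <- function(x, n_sim = 1000L, percentile = 0.95, seed = 1L) {
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (n_sim < 100L) stop("n_sim must be >= 100")
  n <- nrow(x); p <- ncol(x)
  obs <- pca_eigenvalues(x)
  set.seed(seed)
  sims <- matrix(NA_real_, n_sim, length(obs))
  for (s in seq_len(n_sim)) {
    sims[s, ] <- pca_eigenvalues(matrix(stats::rnorm(n * p), n, p))
  }
  thr <- apply(sims, 2, stats::quantile, probs = percentile, names = FALSE)
  above <- obs > thr
  n_retained <- match(FALSE, above, nomatch = length(above) + 1L) - 1L
  list(n_retained = as.integer(n_retained), eigenvalues = obs, thresholds = thr)
}

# Eigenvalues of the column-covariance (population divisor matches the
# population-SD z-scaling so they sum to the number of features).
pca_eigenvalues <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 0, nv = 0)$d
  ev <- sv^2 / nrow(x)
  c(ev, rep(0, max(0, min(dim(x)) - length(ev))))
}

#' Principal component analysis with a fixed sign convention
#'
#' SVD-based PCA of the sample x feature matrix (covariance of z-scored
#' columns). The sign of each loading vector is fixed so its
#' largest-magnitude element is positive.
#'
#' @param x numeric matrix, samples x features.
#' @return A list with `loadings` (feature x PC), `scores` (sample x PC),
#'   `eigenvalues`, `explained_variance_fraction`.
#' @export
fit_pca <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  ev <- sv$d^2 / nrow(x)
  keep <- seq_len(min(dim(xc)))
  load <- sv$v[, keep, drop = FALSE]
  scores <- xc %*% load
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", keep)
  colnames(scores) <- paste0("PC", keep)
  list(
    loadings = load, scores = scores, eigenvalues = ev[keep],
    explained_variance_fraction = ev[keep] / sum(ev)
  )
}

#' Collapse designated redundant feature families to one representative
#'
#' From each designated family (e.g. hemoglobin-related protein groups), only
#' the named representative is kept; order of the surviving panel is
#' preserved. Families are supplied explicitly: the scientific decision of
#' which features are redundant (and which representative carries the signal
#' the assay already measures) is an input, not inferred.
#'
#' @param feature_ids character panel.
#' @param families named list: each element a character vector of family
#'   members, each name the representative to keep.
#' @return The collapsed panel.
#' @export
redundant_group_collapse <- function(feature_ids, families = list()) {
  if (length(families) == 0L) return(feature_ids)
  drop <- character(0)
  for (rep_id in names(families)) {
    fam <- families[[rep_id]]
    if (!rep_id %in% fam) {
      stop(sprintf("representative %s is not a member of its family", rep_id))
    }
    drop <- c(drop, setdiff(fam, rep_id))
  }
  feature_ids[!feature_ids %in% drop]
}

#' Fit the PCA benchmark classifier
#'
#' PCA on the z-scored panel, parallel-analysis PC retention, and a
#' maximum-likelihood logistic regression of the binary label on the retained
#' PC scores. Deliberately fit on the full dataset with no train/test split:
#' its metrics are an optimistic benchmark, not generalization estimates. On
#' logistic separation (or zero retained PCs) a small ridge stabilizer keeps
#' the fit deterministic and a warning is recorded.
#'
#' @param matrix a z-scored [abundance_matrix()].
#' @param feature_ids panel of protein ids (rows of the matrix).
#' @param labels logical or 0/1 vector over samples (TRUE = case).
#' @param n_sim,percentile,seed parallel-analysis settings.
#' @return An object of class `pca_benchmark` with the PCA, retained count,
#'   logistic coefficients, fitted probabilities and notes.
#' @export
fit_pca_benchmark <- function(matrix, feature_ids, labels, n_sim = 1000L,
                              percentile = 0.95, seed = 1L) {
  check_state(matrix, "zscored", "fit_pca_benchmark")
  missing_f <- setdiff(feature_ids, matrix$protein_ids)
  if (length(missing_f) > 0) {
    stop(sprintf("panel features absent from matrix: %s",
                 paste(missing_f, collapse = ", ")))
  }
  y <- as.integer(as.logical(labels))
  x <- t(matrix$values[feature_ids, , drop = FALSE])  # samples x features
  pa <- parallel_analysis(x, n_sim = n_sim, percentile = percentile,
                          seed = seed)
  pca <- fit_pca(x)
  k <- pa$n_retained
  notes <- character(0)
  if (k == 0L) {
    notes <- c(notes, "parallel analysis retained 0 PCs; intercept-only fit")
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    prob <- rep(unname(stats::fitted(fit)[1]), length(y))
    coefs <- stats::coef(fit)
  } else {
    s <- pca$scores[, seq_len(k), drop = FALSE]
    fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))
    if (!fit$converged || any(abs(stats::coef(fit)) > 1e3)) {
      notes <- c(notes, "separation detected; ridge-stabilized logistic fit")
      gf <- glmnet::glmnet(cbind(s, 0), y, family = "binomial", alpha = 0,
                           lambda = 1e-8, standardize = FALSE)
      b <- as.numeric(stats::coef(gf))[seq_len(k + 1)]
      coefs <- b
      eta <- b[1] + s %*% b[-1]
      prob <- as.numeric(stats::plogis(eta))
    } else {
      coefs <- stats::coef(fit)
      prob <- as.numeric(stats::fitted(fit))
    }
  }
  structure(list(
    pca = list(
      feature_ids = feature_ids, loadings = pca$loadings,
      eigenvalues = pca$eigenvalues,
      explained_variance_fraction = pca$explained_variance_fraction,
      n_retained = k, thresholds = pa$thresholds, scores = pca$scores
    ),
    coefficients = coefs, threshold = 0.5,
    fitted_probabilities = stats::setNames(prob, matrix$sample_ids),
    labels = y, notes = notes
  ), class = "pca_benchmark")
}

#' @export
print.pca_benchmark <- function(x, ...) {
  cat(sprintf(
    "<pca_benchmark> %d features, %d retained PC(s), explained %.1f%%\n",
    length(x$pca$feature_ids), x$pca$n_retained,
    100 * sum(x$pca$explained_variance_fraction[seq_len(x$pca$n_retained)])
  ))
  invisible(x)
}
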