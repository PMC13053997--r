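#' Kernel SHAP attributions
#'
#' Shapley values via the weighted-least-squares kernel formulation. The
#' value of a coalition S for an instance is the mean model output over the
#' background set with the features in S taken from the instance and the
#' rest from each background row (marginal expectation). All 2^M - 2 proper
#' coalitions are enumerated when the feature count M is at most
#' `exact_limit`; beyond that, coalitions are sampled in complementary pairs
#' with probabilities proportional to the Shapley kernel weights of their
#' sizes (singleton and leave-one-out coalitions always included). The
#' efficiency constraint (attributions sum to f(x) - base value) is imposed
#' exactly in the solve, so local accuracy holds for both modes.
#'
#' @param model_predict function taking a samples x features matrix and
#'   returning numeric outputs (e.g. case probabilities).
#' @param background background matrix (rows = reference samples); the
#'   expectation defining the base value is over these rows.
#' @param instances matrix of samples to explain.
#' @param max_coalitions sampling budget when enumeration is not exact
#'   (default 1024, on top of the always-included coalitions).
#' @param seed integer seed for coalition sampling.
#' @param exact_limit enumerate exhaustively up to this many features
#'   (default 12).
#' @return A `shap_summary`: `shap_values` (instances x features),
#'   `base_value`, `predictions`, `mean_abs_shap`, `sd_shap`.
#' @export
kernel_shap <- function(model_predict, background, instances,
                        max_coalitions = 1024L, seed = 1L,
                        exact_limit = 12L) {
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  M <- ncol(instances)
  if (nrow(background) < 1L) stop("background must be non-empty")
  if (ncol(background) != M) stop("background/instance feature mismatch")
  feats <- colnames(instances) %||% sprintf("F%02d", seq_len(M))

  base_value <- mean(model_predict(background))
  fx <- model_predict(instances)

  if (M == 1L) {
    phi <- matrix(fx - base_value, ncol = 1,
                  dimnames = list(NULL, feats))
    return(shap_summary_obj(phi, base_value, fx))
  }

  Z <- coalition_matrix(M, max_coalitions, seed, exact_limit)
  sizes <- rowSums(Z)
  w <- (M - 1) / (choose(M, sizes) * sizes * (M - sizes))

  # v(z) for every coalition and instance
  n_bg <- nrow(background)
  n_inst <- nrow(instances)
  V <- matrix(NA_real_, nrow(Z), n_inst)
  for (k in seq_len(nrow(Z))) {
    on <- Z[k, ] == 1
    # background replicated per instance with coalition features overwritten
    big <- background[rep(seq_len(n_bg), n_inst), , drop = FALSE]
    inst_rep <- instances[rep(seq_len(n_inst), each = n_bg), , drop = FALSE]
    big[, on] <- inst_rep[, on, drop = FALSE]
    preds <- model_predict(big)
    V[k, ] <- colMeans(matrix(preds, n_bg, n_inst))
  }

  # constrained WLS: eliminate the last feature via sum(phi) = fx - base
  A <- Z[, -M, drop = FALSE] - Z[, M]
  WA <- A * w
  AtWA <- crossprod(A, WA)
  phi <- matrix(NA_real_, n_inst, M, dimnames = list(NULL, feats))
  AtW <- t(WA)
  for (i in seq_len(n_inst)) {
    b <- V[, i] - base_value - Z[, M] * (fx[i] - base_value)
    ph <- solve(AtWA, AtW %*% b)
    phi[i, ] <- c(ph, fx[i] - base_value - sum(ph))
  }
  shap_summary_obj(phi, base_value, fx)
}

shap_summary_obj <- function(phi, base_value, fx) {
  structure(list(
    shap_values = phi, base_value = base_value, predictions = fx,
    mean_abs_shap = colMeans(abs(phi)),
    sd_shap = apply(phi, 2, stats::sd)
  ), class = "shap_summary")
}

# Proper coalitions (no empty/full set) as a 0/1 matrix. Exact enumeration up
# to exact_limit features, else paired sampling by kernel-weighted sizes with
# all size-1 and size-(M-1) coalitions included.
coalition_matrix <- function(M, max_coalitions, seed, exact_limit) {
  if (M <= exact_limit) {
    idx <- seq_len(2^M - 2)
    Z <- t(vapply(idx, function(i) as.integer(intToBits(i)[seq_len(M)]),
                  integer(M)))
    return(Z)
  }
  set.seed(seed)
  base_rows <- rbind(diag(M), 1 - diag(M))
  sizes <- 2:(M - 2)
  size_w <- (M - 1) / (sizes * (M - sizes))    # kernel weight mass per size
  n_sample <- max_coalitions
  keys <- character(nrow(base_rows))
  for (i in seq_len(nrow(base_rows))) keys[i] <- paste(base_rows[i, ], collapse = "")
  rows <- base_rows
  tries <- 0L
  while (nrow(rows) < 2 * M + n_sample && tries < 20L * n_sample) {
    tries <- tries + 1L
    s <- sample(sizes, 1L, prob = size_w)
    z <- integer(M)
    z[sample.int(M, s)] <- 1L
    key <- paste(z, collapse = "")
    if (!key %in% keys) {
      rows <- rbind(rows, z, 1L - z)
      keys <- c(keys, key, paste(1L - z, collapse = ""))
    }
  }
  unname(rows)
}

#' Group-stratified SHAP summaries
#'
#' Restricts a [kernel_shap()] result to each diagnostic group and reports
#' per-group mean absolute SHAP and SD, with the global ranking by mean
#' absolute SHAP descending.
#'
#' @param shap a `shap_summary`.
#' @param groups per-explained-sample group labels.
#' @return A list with `global` (data frame ranked by mean_abs_shap) and
#'   `by_group` (the same per group).
#' @export
stratified_shap_summary <- function(shap, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(shap$shap_values)) {
    stop("groups must match explained samples")
  }
  summ <- function(phi) {
    df <- data.frame(
      feature = colnames(phi),
      mean_abs_shap = colMeans(abs(phi)),
      sd_shap = apply(phi, 2, stats::sd),
      row.names = NULL
    )
    df[order(-df$mean_abs_shap), ]
  }
  by_group <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    if (!any(sel)) {
      warning(sprintf("empty group %s skipped", g), call. = FALSE)
      next
    }
    by_group[[g]] <- summ(shap$shap_values[sel, , drop = FALSE])
  }
  list(global = summ(shap$shap_values), by_group = by_group)
}
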