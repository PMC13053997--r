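#' Filter proteins by quantification rate and species inference
#'
#' Retains proteins quantified in at least `min_quant_fraction` of samples
#' (boundary inclusive) whose species inference is human-exclusive or human
#' co-inferred with a dietary species, and that are not flagged for manual
#' exclusion. Row order is preserved.
#'
#' @param matrix an [abundance_matrix()] in `raw` state.
#' @param protein_meta data frame with `protein_id`, `species` (one of
#'   `"human"`, `"human+dietary"`, `"nonhuman"`) and optional logical
#'   `excluded`.
#' @param min_quant_fraction minimum fraction of quantified values (default
#'   0.5).
#' @param species_policy character vector of admissible species labels.
#' @return The filtered [abundance_matrix()].
#' @export
filter_proteins <- function(matrix, protein_meta, min_quant_fraction = 0.5,
                            species_policy = c("human", "human+dietary")) {
  check_state(matrix, "raw", "filter_proteins")
  meta <- protein_meta[match(matrix$protein_ids, protein_meta$protein_id), ]
  quant <- rowMeans(matrix$mask)
  excluded <- if ("excluded" %in% names(meta)) isTRUE_vec(meta$excluded) else FALSE
  keep <- quant >= min_quant_fraction & meta$species %in% species_policy &
    !excluded
  if (!any(keep)) {
    stop(sprintf(
      "no proteins pass filtering (%d failed quantification >= %.2f, %d failed species policy)",
      sum(quant < min_quant_fraction), min_quant_fraction,
      sum(!meta$species %in% species_policy)
    ))
  }
  subset_proteins(matrix, which(keep))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Log2-transform observed intensities
#'
#' @param matrix an [abundance_matrix()] in `raw` state with positive observed
#'   intensities.
#' @return The matrix in `log2` state; the mask is untouched.
#' @export
log2_transform <- function(matrix) {
  check_state(matrix, "raw", "log2_transform")
  bad <- which(matrix$mask & matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive observed intensity at protein %s, sample %s",
                 rownames(matrix$values)[bad[1, 1]],
                 colnames(matrix$values)[bad[1, 2]]))
  }
  update_matrix(matrix, log2(matrix$values), "log2")
}

#' Quantile normalization tolerant of missing cells
#'
#' All complete columns are mapped onto an identical sorted distribution: the
#' across-column mean of order statistics (the reference quantile curve). In a
#' column with missing cells, observed values are ranked among themselves and
#' projected onto the reference curve at their quantile positions by linear
#' interpolation. Ties receive the average of their target quantiles.
#'
#' @param matrix an [abundance_matrix()] in `log2` state.
#' @return The matrix in `normalized` state.
#' @export
quantile_normalize <- function(matrix) {
  check_state(matrix, "log2", "quantile_normalize")
  v <- matrix$values
  n <- nrow(v)
  empty <- colSums(matrix$mask) == 0L
  if (any(empty)) {
    stop(sprintf("column(s) entirely missing: %s",
                 paste(colnames(v)[empty], collapse = ", ")))
  }
  # Reference curve on the full row-count grid: per column, interpolate its
  # observed sorted values onto n equally spaced quantiles, then average.
  grid <- (seq_len(n) - 1) / (n - 1)
  ref <- rowMeans(vapply(seq_len(ncol(v)), function(j) {
    x <- sort(v[matrix$mask[, j], j])
    if (length(x) == 1L) rep(x, n)
    else stats::approx((seq_along(x) - 1) / (length(x) - 1), x, xout = grid)$y
  }, numeric(n)))
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- matrix$mask[, j]
    x <- v[obs, j]
    k <- length(x)
    q <- if (k == 1L) 0.5 else (rank(x, ties.method = "average") - 1) / (k - 1)
    out[obs, j] <- stats::approx(grid, ref, xout = q)$y
  }
  update_matrix(matrix, out, "normalized")
}

#' Assess per-protein batch association
#'
#' Fits a one-way ANOVA of abundance on batch for each protein (observed cells
#' only) and reports the F-test p-value, plus the fraction of proteins with
#' p < 0.05. Proteins for which some batch has fewer than two observed samples
#' get `NA` p-values and are flagged, not dropped.
#'
#' @param matrix an [abundance_matrix()] in `normalized` or `batch_corrected`
#'   state.
#' @param sample_meta data frame with `sample_id` and `batch`.
#' @param alpha significance cut for the reported fraction.
#' @return A list with `p_values`, `flagged` (logical), and
#'   `fraction_significant` (among unflagged proteins).
#' @export
assess_batch <- function(matrix, sample_meta, alpha = 0.05) {
  check_state(matrix, c("normalized", "batch_corrected", "imputed"),
              "assess_batch")
  batch <- factor(sample_meta$batch[match(matrix$sample_ids,
                                          sample_meta$sample_id)])
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  p <- apply_rows(matrix, function(x, obs) {
    tb <- table(batch[obs])               # counts over all batch levels
    if (any(tb < 2L)) return(NA_real_)
    fit <- stats::oneway.test(x[obs] ~ batch[obs], var.equal = TRUE)
    unname(fit$p.value)
  })
  flagged <- is.na(p)
  list(
    p_values = p, flagged = flagged,
    fraction_significant = mean(p[!flagged] < alpha)
  )
}

apply_rows <- function(matrix, f) {
  out <- vapply(seq_len(nrow(matrix$values)), function(i) {
    f(matrix$values[i, ], matrix$mask[i, ])
  }, numeric(1))
  stats::setNames(out, matrix$protein_ids)
}

#' Empirical-Bayes location/scale batch correction
#'
#' ComBat-style parametric adjustment that tolerates missing cells (which stay
#' missing). Per protein, abundances are standardized against a batch-design
#' least-squares fit and pooled variance; per-batch location (gamma) and scale
#' (delta^2) parameters are shrunk toward batch-level priors (normal prior for
#' gamma, inverse-gamma for delta^2, moment-matched as in parametric ComBat)
#' by iterating the posterior-mean equations; the standardized data are then
#' adjusted and restored. Diagnostic group labels are deliberately not used as
#' covariates; when batch and group are confounded this risks removing group
#' signal, and a warning notes it.
#'
#' @param matrix an [abundance_matrix()] in `normalized` state.
#' @param sample_meta data frame with `sample_id` and `batch`.
#' @param parametric use parametric EB priors (the only implemented mode;
#'   kept as an argument for interface stability).
#' @return The matrix in `batch_corrected` state.
#' @export
correct_batch <- function(matrix, sample_meta, parametric = TRUE) {
  check_state(matrix, "normalized", "correct_batch")
  batch <- factor(sample_meta$batch[match(matrix$sample_ids,
                                          sample_meta$sample_id)])
  n_batches <- nlevels(batch)
  if (n_batches < 2L) {
    # single batch: nothing to correct
    return(update_matrix(matrix, matrix$values, "batch_corrected"))
  }
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop(sprintf("batch(es) of size 1: %s (variance inestimable)",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  warning("batch correction does not protect group covariates; ",
          "confounded group signal may be removed", call. = FALSE)

  v <- matrix$values
  mask <- matrix$mask
  n_p <- nrow(v)
  bl <- levels(batch)

  # Per-protein batch means on observed cells and pooled residual variance.
  gamma_hat <- matrix(NA_real_, n_p, n_batches)
  for (b in seq_len(n_batches)) {
    sel <- batch == bl[b]
    m <- mask[, sel, drop = FALSE]
    x <- v[, sel, drop = FALSE]
    x[!m] <- NA
    gamma_hat[, b] <- rowMeans(x, na.rm = TRUE)
  }
  n_obs_b <- vapply(seq_len(n_batches), function(b) {
    rowSums(mask[, batch == bl[b], drop = FALSE])
  }, numeric(n_p))
  if (any(n_obs_b < 1)) {
    # proteins with an empty batch: leave those batch params at overall mean
    gamma_hat[n_obs_b < 1] <- 0
  }
  w <- n_obs_b / rowSums(n_obs_b)
  grand <- rowSums(gamma_hat * w, na.rm = TRUE)
  resid <- v - gamma_hat[, as.integer(batch)]
  resid[!mask] <- NA
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / pmax(rowSums(mask) - 1, 1)
  var_pooled[var_pooled <= 0] <- min(var_pooled[var_pooled > 0], 1e-8)

  z <- (v - grand) / sqrt(var_pooled)   # standardized data
  z[!mask] <- NA

  z_adj <- z
  for (b in seq_len(n_batches)) {
    sel <- batch == bl[b]
    zb <- z[, sel, drop = FALSE]
    g_hat <- rowMeans(zb, na.rm = TRUE)
    nb <- rowSums(!is.na(zb))
    d_hat <- rowSums((zb - g_hat)^2, na.rm = TRUE) / pmax(nb - 1, 1)
    ok <- nb >= 2 & is.finite(g_hat) & is.finite(d_hat) & d_hat > 0
    # moment-matched priors across proteins
    g_bar <- mean(g_hat[ok]); t2 <- stats::var(g_hat[ok])
    m_d <- mean(d_hat[ok]); v_d <- stats::var(d_hat[ok])
    a_prior <- (2 * v_d + m_d^2) / v_d
    b_prior <- (m_d * v_d + m_d^3) / v_d
    if (!is.finite(t2) || t2 <= 0 || !is.finite(v_d) || v_d <= 0) {
      g_star <- g_hat; d_star <- d_hat
    } else {
      # iterate the parametric posterior-mean equations
      g_star <- g_hat; d_star <- d_hat
      for (iter in 1:50) {
        g_new <- (t2 * nb * g_hat + d_star * g_bar) / (t2 * nb + d_star)
        ssq <- rowSums((zb - g_new)^2, na.rm = TRUE)
        d_new <- (0.5 * ssq + b_prior) / (nb / 2 + a_prior - 1)
        if (max(abs(g_new - g_star), na.rm = TRUE) < 1e-8 &&
            max(abs(d_new - d_star), na.rm = TRUE) < 1e-8) {
          g_star <- g_new; d_star <- d_new; break
        }
        g_star <- g_new; d_star <- d_new
      }
    }
    g_star[!ok] <- 0; d_star[!ok | d_star <= 0] <- 1
    z_adj[, sel] <- (zb - g_star) / sqrt(d_star)
  }
  out <- z_adj * sqrt(var_pooled) + grand
  out[!mask] <- NA
  update_matrix(matrix, out, "batch_corrected")
}

#' K-nearest-neighbour imputation across samples
#'
#' Each missing cell (protein p, sample s) is filled with the mean of p's
#' observed values in the k samples nearest to s. Distance between two samples
#' is the Euclidean distance over proteins observed in both, rescaled by
#' `sqrt(fraction observed)` to correct for unequal overlap. A sample sharing
#' no observed proteins with any other falls back to the protein-wise mean
#' (logged via a message). Observed cells are never altered; the mask keeps
#' the original observation record.
#'
#' @param matrix an [abundance_matrix()] in `batch_corrected` (or
#'   `normalized`) state.
#' @param k number of neighbours (default 10); must be < number of samples.
#' @return The matrix in `imputed` state with no remaining `NA`.
#' @export
knn_impute <- function(matrix, k = 10L) {
  check_state(matrix, c("normalized", "batch_corrected"), "knn_impute")
  n_s <- ncol(matrix$values)
  if (k >= n_s) stop(sprintf("k = %d must be < number of samples (%d)", k, n_s))
  v <- matrix$values
  mask <- matrix$mask
  if (all(mask)) return(update_matrix(matrix, v, "imputed"))

  # pairwise distances over mutually observed proteins
  vz <- v; vz[!mask] <- 0
  mnum <- mask * 1
  overlap <- crossprod(mnum)                       # mutually observed counts
  sq <- vz^2
  cross <- crossprod(vz)
  ssum <- crossprod(sq, mnum)                      # sum_i v_i^2 over mutual obs
  d2 <- ssum + t(ssum) - 2 * cross
  d2[d2 < 0] <- 0
  n_p <- nrow(v)
  # Euclidean over shared proteins, / sqrt(fraction observed) to make
  # distances with sparse overlap comparable (upscales to full-length norm)
  D <- sqrt(d2) / sqrt(pmax(overlap, 1) / n_p)
  D[overlap == 0] <- Inf
  diag(D) <- Inf

  row_means <- rowSums(vz) / pmax(rowSums(mnum), 1)
  out <- v
  for (s in which(colSums(!mask) > 0)) {
    miss_p <- which(!mask[, s])
    ds <- D[, s]
    if (all(!is.finite(ds))) {
      message(sprintf("sample %s shares no observed proteins; protein-mean fallback",
                      colnames(v)[s]))
      out[miss_p, s] <- row_means[miss_p]
      next
    }
    ord <- order(ds)
    for (p in miss_p) {
      nb <- ord[mask[p, ord]][seq_len(k)]
      nb <- nb[!is.na(nb)]
      out[p, s] <- if (length(nb) > 0) mean(v[p, nb]) else row_means[p]
    }
  }
  update_matrix(matrix, out, "imputed")
}

#' Z-score each protein across samples
#'
#' Centres each protein row to mean 0 and scales it to population SD 1
#' (divisor n, a fixed convention for reproducibility).
#'
#' @param matrix an [abundance_matrix()] in `imputed` (or `zscored`, for
#'   idempotence) state.
#' @return The matrix in `zscored` state.
#' @export
zscore <- function(matrix) {
  check_state(matrix, c("imputed", "zscored"), "zscore")
  v <- matrix$values
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  zero <- sd_pop == 0
  if (any(zero)) {
    stop(sprintf("zero-variance protein(s): %s",
                 paste(rownames(v)[zero], collapse = ", ")))
  }
  update_matrix(matrix, (v - mu) / sd_pop, "zscored")
}

#' Run the full five-step preprocessing pipeline
#'
#' Filter -> log2 -> quantile normalization -> batch assessment + EB batch
#' correction -> KNN imputation (k = 10) -> z-scaling. Returns every
#' intermediate of downstream interest: the imputed (pre-z-score) matrix is
#' the scale on which log2 fold changes are meaningful, while the z-scored
#' matrix feeds PCA, feature selection and classification.
#'
#' @param matrix raw [abundance_matrix()].
#' @param sample_meta sample metadata (sample_id, group, batch).
#' @param protein_meta protein metadata (protein_id, species, excluded).
#' @param min_quant_fraction quantification-rate filter (default 0.5).
#' @param k imputation neighbours (default 10).
#' @return A list with `zscored`, `imputed`, `normalized` matrices, the
#'   `batch_report` (pre- and post-correction), and per-step counts.
#' @export
preprocess_pipeline <- function(matrix, sample_meta, protein_meta,
                                min_quant_fraction = 0.5, k = 10L) {
  filtered <- filter_proteins(matrix, protein_meta, min_quant_fraction)
  lg <- log2_transform(filtered)
  norm <- quantile_normalize(lg)
  batch_pre <- assess_batch(norm, sample_meta)
  corrected <- suppressWarnings(correct_batch(norm, sample_meta))
  batch_post <- assess_batch(corrected, sample_meta)
  imputed <- knn_impute(corrected, k = k)
  z <- zscore(imputed)
  list(
    zscored = z, imputed = imputed, normalized = norm,
    batch_report = list(pre = batch_pre, post = batch_post),
    counts = list(
      proteins_in = nrow(matrix$values),
      proteins_retained = nrow(z$values),
      samples = ncol(z$values),
      cells_imputed = sum(!imputed$mask),
      quantification_rate = mean(filtered$mask)
    )
  )
}
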