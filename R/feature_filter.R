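#' Apply a manual exclusion list to a panel
#'
#' Set difference preserving panel order. Excluding an id not present in the
#' panel raises a warning, not an error (the exclusion list typically comes
#' from manual spectral review of a longer candidate list).
#'
#' @param panel character vector of feature ids.
#' @param exclusion_ids ids to remove.
#' @return The reduced panel.
#' @export
apply_exclusion_list <- function(panel, exclusion_ids) {
  unknown <- setdiff(exclusion_ids, panel)
  if (length(unknown) > 0) {
    warning(sprintf("exclusion id(s) not in panel: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  panel[!panel %in% exclusion_ids]
}

#' Iterative VIF-based multicollinearity pruning
#'
#' VIF_j = 1/(1 - R^2_j), with R^2_j from regressing feature j on all other
#' panel features. The highest-VIF feature not protected by
#' `keep_preferences` is removed and VIFs are recomputed, until every VIF is
#' below `threshold`. Perfect collinearity gives VIF = Inf and that feature
#' is removed first (unless protected). Every removal step is reported.
#'
#' @param matrix a z-scored [abundance_matrix()] (proteins x samples).
#' @param panel feature ids to assess.
#' @param threshold VIF threshold (default 10).
#' @param keep_preferences features never removed (e.g. the representative of
#'   a known collinear family).
#' @return A list with `panel` (retained, order preserved) and `report`
#'   (`iterations` data frame and `final_vifs`).
#' @export
vif_prune <- function(matrix, panel, threshold = 10, keep_preferences = character(0)) {
  x <- t(matrix$values[panel, , drop = FALSE])
  current <- panel
  iters <- data.frame(feature_removed = character(0), vif_at_removal = numeric(0))
  repeat {
    vifs <- compute_vifs(x[, current, drop = FALSE])
    removable <- setdiff(current, keep_preferences)
    # an infinite threshold means report-only: nothing is ever pruned
    cand <- if (is.finite(threshold)) {
      removable[vifs[removable] >= threshold]
    } else character(0)
    if (length(current) <= 2L || length(cand) == 0L) break
    worst <- cand[which.max(vifs[cand])]
    iters <- rbind(iters, data.frame(feature_removed = worst,
                                     vif_at_removal = vifs[worst]))
    current <- setdiff(current, worst)
  }
  final <- compute_vifs(x[, current, drop = FALSE])
  list(panel = current,
       report = list(iterations = iters, final_vifs = final))
}

# VIFs by per-feature least squares; rank-deficient fits give R^2 = 1 -> Inf.
compute_vifs <- function(x) {
  p <- ncol(x)
  ids <- colnames(x)
  if (p < 2L) return(stats::setNames(rep(1, p), ids))
  vapply(stats::setNames(seq_len(p), ids), function(j) {
    yj <- x[, j]
    xj <- x[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, xj), yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Robust outlier flagging (ROUT, constant-model form)
#'
#' The cited robust-regression-and-outlier-removal procedure specialised to a
#' single column of values per feature and class (the constant model): robust
#' location = median; robust scale = the 68.27th percentile of absolute
#' residuals with the small-n correction n/(n - 1); residuals are then tested
#' outermost-first with t-based p-values (df = n - 1) against a
#' false-discovery step comparing the i-th outermost p-value to
#' `Q * i / n`. Values are flagged, never removed here.
#'
#' @param values numeric vector (one feature within one class).
#' @param Q FDR level (default 0.01, i.e. 1%).
#' @return Logical vector of flags (same length/order as `values`).
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  flags <- rep(FALSE, n)
  if (n < 5L) {
    warning("fewer than 5 values; no outlier test performed", call. = FALSE)
    return(flags)
  }
  r <- values - stats::median(values)
  rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr <= 0) return(flags)          # degenerate: identical values
  ord <- order(abs(r), decreasing = TRUE)
  tt <- abs(r[ord]) / rsdr
  p <- 2 * stats::pt(tt, df = n - 1, lower.tail = FALSE)
  # flag the largest k outermost residuals whose p-values all pass Q*i/n;
  # only a leading run can be flagged (outermost-first)
  k <- 0L
  for (i in seq_len(floor(n / 2))) {
    if (p[i] < Q * i / n) k <- i else break
  }
  if (k > 0L) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Per-feature, per-class outlier flags for a panel
#'
#' Applies [rout_outliers()] to each panel feature within each class and
#' returns the flags in long format.
#'
#' @param matrix an [abundance_matrix()].
#' @param panel feature ids.
#' @param classes named list mapping class label -> sample ids (or a factor
#'   over samples).
#' @param Q FDR level (default 0.01).
#' @return A data frame `feature`, `class`, `sample_id`, `flagged`
#'   (flagged rows only), plus attribute `n_flagged`.
#' @export
panel_outlier_flags <- function(matrix, panel, classes, Q = 0.01) {
  if (is.factor(classes) || is.character(classes)) {
    cl <- split(matrix$sample_ids, classes)
  } else cl <- classes
  out <- list()
  for (f in panel) {
    for (lab in names(cl)) {
      sids <- intersect(cl[[lab]], matrix$sample_ids)
      v <- matrix$values[f, sids]
      fl <- suppressWarnings(rout_outliers(v, Q = Q))
      if (any(fl)) {
        out[[length(out) + 1L]] <- data.frame(
          feature = f, class = lab, sample_id = sids[fl], flagged = TRUE
        )
      }
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(feature = character(0), class = character(0),
               sample_id = character(0), flagged = logical(0))
  attr(res, "n_flagged") <- nrow(res)
  res
}
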