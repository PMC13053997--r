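#' Mann-Whitney U test for two groups
#'
#' Two-sided rank-sum test. The p-value comes from exact enumeration when the
#' combined sample size is at most 12 and there are no ties, and otherwise
#' from the normal approximation with tie correction and continuity
#' correction. `U` is reported for the first group (number of (a, b) pairs
#' with a > b, ties counting 1/2).
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return A list with `U` and `p`.
#' @export
mann_whitney_u <- function(values_a, values_b) {
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both groups must be non-empty")
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (n_a + n_b) <= 12L && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided",
    exact = exact, correct = TRUE
  ))
  list(U = unname(ht$statistic), p = min(ht$p.value, 1))
}

#' Benjamini-Krieger-Yekutieli two-stage adaptive FDR
#'
#' Two-stage linear step-up at level `q_level`: stage 1 is BH at
#' q' = q/(1+q) giving r1 rejections; if r1 is 0 or m the procedure stops
#' there; otherwise the null count is estimated as m - r1 and stage 2 is BH at
#' level q' * m / (m - r1). Per-test q-values are defined operationally as the
#' smallest nominal level at which the two-stage procedure rejects that test,
#' found by bisection to 1e-6.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q_level nominal FDR level (default 0.05).
#' @param compute_q compute per-test q-values by bisection (default TRUE);
#'   disable in large simulation loops where only the rejection set matters.
#' @return A list with `discoveries` (logical), `q_values` (`NULL` when
#'   disabled), and `n_discoveries`.
#' @export
bky_fdr <- function(p_values, q_level = 0.05, compute_q = TRUE) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  rej <- bky_reject(p_values, q_level)
  if (!compute_q) {
    return(list(discoveries = rej, q_values = NULL,
                n_discoveries = sum(rej)))
  }
  q_values <- vapply(seq_along(p_values), function(i) {
    if (is.na(p_values[i])) return(NA_real_)
    lo <- 0; hi <- 1
    # smallest level at which test i is rejected (rejection is monotone in q)
    if (!bky_reject(p_values, 1 - 1e-12)[i]) return(1)
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (bky_reject(p_values, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  list(discoveries = rej, q_values = q_values, n_discoveries = sum(rej))
}

# Rejection set of the two-stage step-up at nominal level q.
bky_reject <- function(p, q) {
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(FALSE, length(p))
  if (m == 0L) return(out)
  q1 <- q / (1 + q)
  r1 <- bh_count(p[ok], q1)
  if (r1 == 0L) return(out)
  r <- if (r1 == m) r1 else bh_count(p[ok], q1 * m / (m - r1))
  if (r > 0L) {
    thr <- sort(p[ok])[r]
    out[ok] <- p[ok] <= thr
  }
  out
}

# Number of BH step-up rejections at level q.
bh_count <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  below <- which(ps <= seq_len(m) / m * q)
  if (length(below) == 0L) 0L else max(below)
}

#' Differential abundance table (case groups vs control)
#'
#' Runs the Mann-Whitney U test per protein between the pooled case groups
#' (default G2 and G3) and the control group (G1), applies the BKY two-stage
#' FDR, and reports the log2 fold change of group means. Because z-scaling is
#' a per-protein monotone map, p-values are identical whether computed on the
#' imputed (pre-z-score) or z-scored matrix; fold changes are only meaningful
#' pre-z-score, so pass the imputed matrix.
#'
#' @param matrix an [abundance_matrix()] (typically `imputed` state, log2
#'   scale).
#' @param sample_meta data frame with `sample_id` and `group`.
#' @param case_groups groups pooled as cases (default `c("G2", "G3")`).
#' @param control_group control group label (default `"G1"`).
#' @param q_level FDR level (default 0.05).
#' @param alpha p-value cut used for the direction call (default 0.05).
#' @return A data frame with one row per protein: `protein_id`, `u_statistic`,
#'   `p_value`, `q_value`, `log2_fold_change`, `direction`.
#' @export
build_da_table <- function(matrix, sample_meta,
                           case_groups = c("G2", "G3"), control_group = "G1",
                           q_level = 0.05, alpha = 0.05) {
  grp <- sample_meta$group[match(matrix$sample_ids, sample_meta$sample_id)]
  is_case <- grp %in% case_groups
  is_ctrl <- grp %in% control_group
  if (!any(is_case) || !any(is_ctrl)) stop("case or control group absent")
  v <- matrix$values
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    a <- v[i, is_case]
    b <- v[i, is_ctrl]
    mw <- mann_whitney_u(a, b)
    c(U = mw$U, p = mw$p, lfc = mean(a) - mean(b))
  }, numeric(3)))
  fdr <- bky_fdr(res[, "p"], q_level)
  direction <- ifelse(
    res[, "p"] <= alpha,
    ifelse(res[, "lfc"] > 0, "up_in_case", "down_in_case"),
    "none"
  )
  data.frame(
    protein_id = matrix$protein_ids,
    u_statistic = res[, "U"],
    p_value = res[, "p"],
    q_value = fdr$q_values,
    log2_fold_change = res[, "lfc"],
    direction = direction,
    stringsAsFactors = FALSE
  )
}

# Vectorized normal-approximation MWU p-values for a matrix of proteins
# (rows) against a binary grouping; used by calibration simulations where
# thousands of tests are needed.
mwu_p_matrix <- function(values, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  n <- n1 + n2
  r <- t(apply(values, 1, rank))
  R1 <- rowSums(r[, is_case, drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per row (skipped for tie-free rows)
  tie_term <- apply(values, 1, function(x) {
    if (anyDuplicated(x) == 0L) return(0)
    tt <- table(x); sum(tt^3 - tt)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)
  pmin(2 * stats::pnorm(-pmax(z, 0)), 1)
}
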