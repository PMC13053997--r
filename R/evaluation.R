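#' Confusion-matrix metrics at a probability threshold
#'
#' Counts and derived rates for a binary classifier. Rates are stored at full
#' precision; `display` strings round half-up to whole percents, mirroring
#' how such results are reported in print.
#'
#' @param scores predicted case probabilities in \[0, 1\] (or counts via
#'   [confusion_from_counts()]).
#' @param labels binary labels (1/TRUE = case).
#' @param threshold probability cut (default 0.5; score >= threshold = case).
#' @return A list with counts `tp`, `fp`, `tn`, `fn`, rates `sensitivity`,
#'   `specificity`, `balanced_accuracy` (full precision, in \[0,1\]),
#'   `display` (whole-percent strings), and `flagged` when labels are
#'   single-class.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  confusion_from_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Confusion metrics from raw counts
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return See [confusion_metrics()].
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  flagged <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    flagged <- c(flagged, "no positives"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    flagged <- c(flagged, "no negatives"); NA_real_
  }
  ba <- (sens + spec) / 2
  pct <- function(x) {
    if (is.na(x)) "NA" else sprintf("%d%%", round_half_up(100 * x))
  }
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, balanced_accuracy = ba,
    display = list(sensitivity = pct(sens), specificity = pct(spec),
                   balanced_accuracy = pct(ba)),
    flagged = flagged
  )
}

# AUROC by the rank (Mann-Whitney) formulation with half credit for ties.
auroc_rank <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values and variance for one score vector.
delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  list(auc = mean(psi), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve, AUROC and DeLong 95% confidence interval
#'
#' AUROC uses the rank (Mann-Whitney) formulation with half credit for ties;
#' the confidence interval uses the DeLong variance estimator, truncated to
#' \[0, 1\]. ROC coordinates are computed at every distinct score.
#'
#' @param scores predicted case scores.
#' @param labels binary labels (1/TRUE = case).
#' @return A list with `auroc`, `ci_95` (low, high), `roc` (data frame of
#'   threshold, sensitivity, specificity), and `degenerate` flag when all
#'   scores tie.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  degenerate <- length(unique(scores)) == 1L
  a <- auroc_rank(scores, y)
  dc <- delong_components(scores, y)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  half <- 1.959963984540054 * sqrt(max(v, 0))
  ci <- c(max(0, a - half), min(1, a + half))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[y == 1] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[y == 0] < t), 0)
  )
  list(auroc = a, ci_95 = ci, roc = roc, degenerate = degenerate)
}

#' Youden-optimal operating threshold
#'
#' Maximizes sensitivity + specificity - 1 over the ROC coordinates; ties go
#' to the lowest threshold.
#'
#' @param roc data frame from [roc_auc()] (`threshold`, `sensitivity`,
#'   `specificity`).
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_threshold <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(roc$threshold[best])]
  list(threshold = roc$threshold[pick], sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick], youden_j = j[pick])
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided p-value for the AUROC difference of two score vectors on the
#' same samples, using the paired DeLong z-statistic. A zero variance of the
#' difference (e.g. identical scores) returns p = 1 with a flag.
#'
#' @param scores_a,scores_b score vectors over the same samples.
#' @param labels binary labels (1/TRUE = case).
#' @return A list with `auc_a`, `auc_b`, `z`, `p_value`, `flagged`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    stop("score vectors must cover the same samples")
  }
  da <- delong_components(scores_a, y)
  db <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= 1e-16) {
    return(list(auc_a = da$auc, auc_b = db$auc, z = 0, p_value = 1,
                flagged = "zero variance of AUROC difference"))
  }
  z <- (da$auc - db$auc) / sqrt(var_diff)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), flagged = character(0))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values via [stats::p.adjust()].
#'
#' @param p_values p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Full evaluation report for a score vector
#'
#' Confusion metrics at the threshold, AUROC with DeLong CI, Youden-optimal
#' operating point, and subgroup reports (each case group alone vs control)
#' when 3-level groups are supplied.
#'
#' @param scores predicted case probabilities.
#' @param labels binary labels (1 = case).
#' @param threshold probability cut (default 0.5).
#' @param groups optional per-sample diagnostic group (e.g. G1/G2/G3) for
#'   subgroup ROC reports.
#' @param control_group group treated as control (default "G1").
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5, groups = NULL,
                              control_group = "G1") {
  cm <- confusion_metrics(scores, labels, threshold)
  ra <- roc_auc(scores, labels)
  yt <- youden_threshold(ra$roc)
  sub <- NULL
  if (!is.null(groups)) {
    case_groups <- setdiff(unique(groups[as.logical(labels)]), control_group)
    sub <- lapply(stats::setNames(case_groups, case_groups), function(g) {
      sel <- groups %in% c(g, control_group)
      list(
        confusion = confusion_metrics(scores[sel], groups[sel] == g, threshold),
        roc = roc_auc(scores[sel], groups[sel] == g)
      )
    })
  }
  structure(list(
    confusion = cm, auroc = ra$auroc, auroc_ci_95 = ra$ci_95, roc = ra$roc,
    youden = yt, subgroups = sub, threshold = threshold
  ), class = "evaluation_report")
}
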