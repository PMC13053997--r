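test_that("confusion metrics reproduce the screening worked example", {
  # 37/50 controls and 83/91 cases correct
  cm <- confusion_from_counts(tp = 83, fp = 13, tn = 37, fn = 8)
  expect_equal(100 * cm$specificity, 74)
  expect_equal(100 * cm$sensitivity, 100 * 83 / 91)
  expect_equal(round(100 * cm$sensitivity, 1), 91.2)
  expect_equal(round(100 * cm$balanced_accuracy, 1), 82.6)
  expect_identical(cm$display$specificity, "74%")
  expect_identical(cm$display$balanced_accuracy, "83%")

  # G2-only sensitivity 37/45
  cm2 <- confusion_from_counts(tp = 37, fp = 0, tn = 0, fn = 8)
  expect_equal(round(100 * cm2$sensitivity, 1), 82.2)
  expect_identical(cm2$display$sensitivity, "82%")

  # perfect classifier
  cmp <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(cmp$sensitivity, 1)
  expect_equal(cmp$specificity, 1)
  expect_equal(cmp$balanced_accuracy, 1)

  # single-class labels flagged
  flag <- confusion_metrics(c(0.9, 0.8), c(1, 1))
  expect_true(length(flag$flagged) > 0)
})

test_that("balanced accuracy equals the mean of the two recalls for any matrix", {
  set.seed(60)
  for (i in 1:20) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (counts[1] + counts[4] == 0 || counts[2] + counts[3] == 0) next
    cm <- confusion_from_counts(tp = counts[1], fp = counts[2],
                                tn = counts[3], fn = counts[4])
    expect_equal(cm$balanced_accuracy, (cm$sensitivity + cm$specificity) / 2)
  }
})

test_that("AUROC agrees with pair counting, the U statistic, and invariances", {
  # brute force over 4 case-control pairs: wins 3, loses 1 -> 0.75
  r <- roc_auc(c(0.9, 0.8, 0.85, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auroc, 0.75)

  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auroc, 1.0)

  # identity with the Mann-Whitney U from the DA module
  set.seed(61)
  sc <- rnorm(40); y <- rep(c(1, 0), 20)
  U <- mann_whitney_u(sc[y == 1], sc[y == 0])$U
  expect_equal(roc_auc(sc, y)$auroc, U / (20 * 20))

  # invariance under strictly monotone transforms; complement property
  expect_equal(roc_auc(plogis(sc), y)$auroc, roc_auc(sc, y)$auroc)
  expect_equal(roc_auc(sc, y)$auroc + roc_auc(-sc, y)$auroc, 1)

  # ties: all scores equal -> 0.5, degenerate flag
  rt <- roc_auc(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(rt$auroc, 0.5)
  expect_true(rt$degenerate)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("DeLong CI and AUROC agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  y <- rep(c(1, 0), c(30, 40))
  sc <- rnorm(70) + y
  ours <- roc_auc(sc, y)
  ref <- pROC::roc(y, sc, quiet = TRUE, direction = "<")
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)))
  expect_equal(ours$ci_95[1], ref_ci[1], tolerance = 1e-6)
  expect_equal(ours$ci_95[2], ref_ci[3], tolerance = 1e-6)
})

test_that("Youden threshold matches an exhaustive scan oracle", {
  set.seed(63)
  for (i in 1:10) {
    sc <- round(runif(20), 2)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- roc_auc(sc, y)
    yt <- youden_threshold(r$roc)
    # oracle: scan every candidate threshold
    cand <- c(Inf, sort(unique(sc), decreasing = TRUE))
    j <- vapply(cand, function(t) {
      mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1
    }, numeric(1))
    expect_equal(yt$youden_j, max(j), tolerance = 1e-12)
    best <- min(cand[j >= max(j) - 1e-12])
    expect_equal(yt$threshold, best)
  }
  # perfect classifier: sens = spec = 1
  yt2 <- youden_threshold(roc_auc(c(0.9, 0.8, 0.2), c(1, 1, 0))$roc)
  expect_equal(yt2$sensitivity, 1)
  expect_equal(yt2$specificity, 1)
})

test_that("DeLong test: self-comparison p = 1, informative beats noise, bootstrap agreement", {
  set.seed(64)
  y <- rep(c(1, 0), c(100, 100))
  good <- rnorm(200) + 1.2 * y
  noise <- rnorm(200)
  self <- delong_test(good, good, y)
  expect_equal(self$p_value, 1)
  expect_length(self$flagged, 1)
  expect_lt(delong_test(good, noise, y)$p_value, 0.01)

  # paired-bootstrap oracle on n = 60
  set.seed(65)
  y2 <- rep(c(1, 0), each = 30)
  a <- rnorm(60) + 0.8 * y2
  b <- 0.55 * a + rnorm(60, sd = 0.8)
  dl <- delong_test(a, b, y2)
  B <- 2000
  diffs <- vapply(1:B, function(i) {
    idx <- sample(60, replace = TRUE)
    if (length(unique(y2[idx])) < 2) return(NA_real_)
    auroc_rank(a[idx], y2[idx]) - auroc_rank(b[idx], y2[idx])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  obs <- auroc_rank(a, y2) - auroc_rank(b, y2)
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(dl$p_value - p_boot), 0.05)
})

test_that("DeLong paired test matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  y <- rep(c(1, 0), c(40, 50))
  a <- rnorm(90) + y
  b <- rnorm(90) + 0.5 * y
  ours <- delong_test(a, b, y)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("BH adjustment matches hand step-up examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("evaluation report assembles subgroup ROCs consistently", {
  set.seed(67)
  groups <- rep(c("G1", "G2", "G3"), c(20, 15, 15))
  y <- groups != "G1"
  sc <- plogis(rnorm(50) + 2 * y + 0.5 * (groups == "G3"))
  ev <- evaluation_report(sc, y, groups = groups)
  expect_named(ev$subgroups, c("G2", "G3"))
  expect_true(ev$subgroups$G3$roc$auroc >= ev$subgroups$G2$roc$auroc)
  expect_true(ev$auroc_ci_95[1] <= ev$auroc & ev$auroc <= ev$auroc_ci_95[2])
})
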