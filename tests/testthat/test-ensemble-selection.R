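test_that("Borda aggregation matches the brute-force oracle on random lists", {
  # independent oracle: explicit per-list point summation, then ordering
  oracle <- function(rankings, K) {
    feats <- sort(unique(unlist(rankings)))
    pts <- setNames(numeric(length(feats)), feats)
    for (r in rankings) {
      top <- head(r, K)
      for (i in seq_along(top)) pts[top[i]] <- pts[top[i]] + (K - i + 1)
    }
    pts
  }
  set.seed(100)
  for (case in 1:100) {
    p <- sample(3:8, 1)
    n_lists <- sample(1:5, 1)
    K <- sample(1:p, 1)
    feats <- sprintf("f%02d", 1:p)
    rankings <- lapply(1:n_lists, function(i) sample(feats))
    got <- borda_aggregate(rankings, K = K)
    want <- oracle(rankings, K)
    expect_equal(got$borda_scores[names(want)], want)
    # top_k ordered by non-increasing score
    expect_true(all(diff(got$borda_scores[got$top_k]) <= 0))
    expect_length(got$top_k, min(K, p))
  }
})

test_that("Borda examples: identity, hand case, and anonymity", {
  # 3 lists over {a,b,c,d}, K=3: a=8, b=6, c=4, d=0
  lists <- list(c("a", "b", "c"), c("b", "a", "c"), c("a", "c", "b"))
  r <- borda_aggregate(lists, K = 3, features = c("a", "b", "c", "d"))
  expect_equal(unname(r$borda_scores[c("a", "b", "c")]), c(8, 6, 4))
  expect_equal(unname(r$borda_scores["d"]), 0)
  expect_identical(r$top_k, c("a", "b", "c"))

  # single list: consensus equals the truncated list
  one <- borda_aggregate(list(c("x", "y", "z", "w")), K = 2)
  expect_identical(one$top_k, c("x", "y"))

  # 50 identical rankings: top feature score = 50 * K
  many <- borda_aggregate(rep(list(c("a", "b", "c")), 50), K = 3)
  expect_identical(many$top_k, c("a", "b", "c"))
  expect_equal(unname(many$borda_scores["a"]), 150)

  # anonymity: list order irrelevant
  r2 <- borda_aggregate(rev(lists), K = 3, features = c("a", "b", "c", "d"))
  expect_identical(r$borda_scores, r2$borda_scores)

  expect_error(borda_aggregate(lists, K = 0), "K")
})

test_that("every selector puts an oracle feature first and is deterministic", {
  d <- oracle_feature_data(n = 60, p = 8, seed = 2)
  for (alg in c("rf", "rrf", "boruta", "svm_rfe", "lasso")) {
    r1 <- run_selector(d$x, d$y, alg, seed = 5)
    expect_identical(r1$ranking[1], "F01")
    expect_setequal(r1$ranking, colnames(d$x))
    r2 <- run_selector(d$x, d$y, alg, seed = 5)
    expect_identical(r1$scores, r2$scores)
    expect_identical(r1$ranking, r2$ranking)
  }
  expect_error(run_selector(d$x, d$y, "mystery", 1), "unknown")
})

test_that("lasso concentrates coefficient mass on a duplicated pair but splits it unstably", {
  set.seed(30)
  n <- 120
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 1] <- y * 1.5 + rnorm(n, sd = 0.6)
  x[, 2] <- x[, 1]                          # exact duplicate
  colnames(x) <- sprintf("F%02d", 1:6)
  picks <- vapply(1:12, function(s) {
    sc <- run_selector(x, y, "lasso", seed = s)$scores
    pair <- sc[c("F01", "F02")]
    expect_gt(sum(pair), sum(sc[3:6]))      # mass concentrated on the pair
    which.max(pair)
  }, numeric(1))
  # each individually unstable: the winner varies or mass is shared
  sds <- sapply(1:12, function(s) run_selector(x, y, "lasso", seed = s)$scores[1:2])
  expect_gt(max(apply(sds, 1, sd)), 0)
})

test_that("stability curve hits closed-form endpoints and null behaviour", {
  feats <- sprintf("g%02d", 1:30)
  # all runs identical: curve is 1 everywhere
  same <- rep(list(feats), 5)
  sc <- stability_curve(same, 3, 25)
  expect_true(all(abs(sc$mean_pairwise_spearman - 1) < 1e-12))

  # two runs, top-3 reversed orders of the same 3 features: rho = -1 at k=3
  two <- list(c("a", "b", "c", feats), c("c", "b", "a", feats))
  sc2 <- stability_curve(two, 3, 3)
  expect_equal(sc2$mean_pairwise_spearman[1], -1)

  # independently shuffled rankings: |rho| small at k=25
  set.seed(9)
  shuf <- lapply(1:20, function(i) sample(feats))
  sc3 <- stability_curve(shuf, 25, 25)
  expect_lt(abs(sc3$mean_pairwise_spearman[1]), 0.15)

  expect_error(stability_curve(shuf, 3, 31), "exceeds")
  expect_error(stability_curve(shuf[1], 3, 10), ">= 2")
})

test_that("consensus overlap returns Venn cardinalities", {
  expect_equal(consensus_overlap(c("a", "b", "c"), c("a", "b", "c"))$common, 3)
  expect_equal(consensus_overlap(c("a", "b"), c("x", "y"))$common, 0)
  ov <- consensus_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$pairwise[1, 2], 2L)
  ov3 <- consensus_overlap(c("a", "b", "c"), c("b", "c", "d"), c("c", "d", "e"))
  expect_equal(ov3$common, 1)
  expect_error(consensus_overlap(c("a")), ">= 2")
})

test_that("two-level aggregation and options produce sane modified-model variants", {
  d <- oracle_feature_data(n = 50, p = 6, seed = 3)
  sel <- run_ensemble_selection(d$x, d$y, algorithms = c("rf", "lasso"),
                                runs = 3, K = 4, seed_base = 10)
  expect_length(sel$consensus$top_k, 4)
  expect_identical(sel$consensus$top_k[1], "F01")
  expect_named(sel$per_algorithm, c("rf", "lasso"))
  expect_length(sel$runs$rf, 3)
  # confirmed-only boruta and bootstrapped lasso still rank the oracle first
  rb <- run_selector(d$x, d$y, "boruta", seed = 2,
                     options = list(confirmed_only = TRUE))
  expect_identical(rb$ranking[1], "F01")
  rl <- run_selector(d$x, d$y, "lasso", seed = 2,
                     options = list(bootstrap = TRUE))
  expect_identical(rl$ranking[1], "F01")
  rr <- run_selector(d$x, d$y, "svm_rfe", seed = 2,
                     options = list(bootstrap = TRUE))
  expect_identical(rr$ranking[1], "F01")
})
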