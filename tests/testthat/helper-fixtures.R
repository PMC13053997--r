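# Shared fixtures, built in code. The default cohort (study conditions) is
# generated once per test run and cached; small toys are built inline.

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()                       # documented defaults, seed 1
      coh <- generate_cohort(cfg)
      coh$matrix <- inject_missingness(coh$matrix, cfg$missing_rate_target,
                                       cfg$mnar_weight, seed = cfg$seed + 1L)
      coh$prep <- preprocess_pipeline(coh$matrix, coh$sample_meta,
                                      coh$protein_meta)
      coh$config <- cfg
      cache <<- coh
    }
    cache
  }
})

# tiny abundance matrix in a given state
toy_matrix <- function(values, state = "raw") {
  abundance_matrix(values, scale_state = state)
}

# samples x features matrix with one informative feature and noise
oracle_feature_data <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- y * 2 + rnorm(n, sd = 0.1)         # near-deterministic in y
  colnames(x) <- sprintf("F%02d", seq_len(p))
  list(x = x, y = y)
}

# brute-force Shapley values by enumeration over all feature subsets
brute_force_shapley <- function(predict_fn, background, instance) {
  M <- length(instance)
  v <- function(S) {
    X <- background
    if (length(S) > 0) X[, S] <- matrix(instance[S], nrow(X), length(S),
                                        byrow = TRUE)
    mean(predict_fn(X))
  }
  phi <- numeric(M)
  for (j in seq_len(M)) {
    others <- setdiff(seq_len(M), j)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in subsets) phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  phi
}

# re-tag a matrix state (testing idempotence without exporting internals)
update_state_for_test <- function(m, state) {
  abundance_matrix(m$values, scale_state = state, mask = m$mask)
}
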