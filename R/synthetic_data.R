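#' Configuration for the synthetic FIT-proteomics cohort
#'
#' The defaults emulate the structure of the screening cohort the pipeline was
#' designed for: 141 FIT-positive samples in three diagnostic groups
#' (G1 = false positives n=50, G2 = advanced adenoma n=45, G3 = carcinoma
#' n=46) acquired in four balanced batches, with ~334 retained protein groups
#' quantified in ~78% of cells overall. A small set of proteins carries planted
#' group effects (both directions), one hemoglobin-like block of highly
#' collinear proteins carries a shared up-shift, ~25% of proteins carry batch
#' location/scale effects, missingness is abundance dependent, and a few gross
#' outliers are planted. Effect and variance magnitudes are documented
#' placeholders (the field rarely reports them); see the methods vignette.
#'
#' @param n_per_group integer triple: samples in G1, G2, G3.
#' @param n_proteins number of protein groups.
#' @param n_batches number of acquisition batches, assigned round-robin within
#'   group so batches stay balanced across groups.
#' @param n_da number of planted differentially abundant proteins.
#' @param effect_sizes signed log2 shifts (G3 vs G1) for the planted proteins;
#'   length `n_da`. G2 receives `g2_fraction` of each shift.
#' @param g2_fraction fraction of the G3 effect applied to G2 (adenomas show
#'   more subtle alterations than carcinomas).
#' @param collinear_block_size size of the collinear (hemoglobin-like) block.
#' @param collinear_rho target mean pairwise correlation within the block.
#' @param block_effect shared log2 up-shift (G3 vs G1) carried by the block.
#' @param batch_affected_fraction fraction of proteins with batch effects.
#' @param batch_shift_sd,batch_scale_sd SD of per-(protein,batch) location
#'   shifts (log2 units) and of log-scale multipliers.
#' @param missing_rate_target overall fraction of missing cells after
#'   [inject_missingness()].
#' @param mnar_weight in \[0,1\]: strength of abundance-dependent missingness
#'   (0 = completely at random).
#' @param outlier_rate fraction of cells receiving a gross +/- 6 log2-unit
#'   perturbation.
#' @param seed integer seed; identical config + seed gives identical cohorts.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(50L, 45L, 46L),
                       n_proteins = 334L,
                       n_batches = 4L,
                       n_da = 15L,
                       effect_sizes = NULL,
                       g2_fraction = 0.6,
                       collinear_block_size = 5L,
                       collinear_rho = 0.995,
                       block_effect = 1.4,
                       batch_affected_fraction = 0.25,
                       batch_shift_sd = 0.8,
                       batch_scale_sd = 0.15,
                       missing_rate_target = 0.22,
                       mnar_weight = 0.5,
                       outlier_rate = 0.002,
                       seed = 1L) {
  if (is.null(effect_sizes)) {
    effect_sizes <- default_effect_sizes(n_da)
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_proteins = as.integer(n_proteins),
    n_batches = as.integer(n_batches), n_da = as.integer(n_da),
    effect_sizes = as.numeric(effect_sizes), g2_fraction = g2_fraction,
    collinear_block_size = as.integer(collinear_block_size),
    collinear_rho = collinear_rho, block_effect = block_effect,
    batch_affected_fraction = batch_affected_fraction,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    missing_rate_target = missing_rate_target, mnar_weight = mnar_weight,
    outlier_rate = outlier_rate, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# 9 up / 6 down by default at n_da = 15, |log2 effect| in [1.2, 2].
default_effect_sizes <- function(n_da) {
  if (n_da == 0L) return(numeric(0))
  n_up <- ceiling(0.6 * n_da)
  mags <- seq(2.0, 1.2, length.out = n_da)
  sign <- rep(c(1, -1), c(n_up, n_da - n_up))
  mags * sign
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(n_per_group) != 3L || any(n_per_group <= 0L)) {
      stop("n_per_group must be three positive counts")
    }
    if (n_proteins <= 0L || n_batches <= 0L) stop("counts must be positive")
    if (length(effect_sizes) != n_da) {
      stop(sprintf("effect_sizes has length %d but n_da = %d",
                   length(effect_sizes), n_da))
    }
    if (n_da + collinear_block_size > n_proteins) {
      stop("n_da + collinear_block_size exceeds n_proteins")
    }
    fr <- c(batch_affected_fraction, missing_rate_target, mnar_weight,
            outlier_rate, g2_fraction)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (collinear_rho < 0 || collinear_rho >= 1) {
      stop("collinear_rho must lie in [0, 1)")
    }
  })
  invisible(cfg)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces a fully observed raw-intensity matrix (log-normal base signal with
#' protein-specific locations), sample and protein metadata, and the ground
#' truth needed for recovery testing. Planted proteins are shifted in G2/G3 vs
#' G1 by the configured log2 effects; the collinear block is driven by a shared
#' latent factor achieving the target mean pairwise correlation; batch
#' location/scale effects touch the configured fraction of proteins; batches
#' are assigned round-robin within group so per-group batch counts differ by at
#' most one. Deterministic given the config seed.
#'
#' Missingness is *not* injected here; call [inject_missingness()] on the
#' result to reach the configured quantification rate.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (an [abundance_matrix()] in `raw` state),
#'   `sample_meta` (sample_id, group, batch), `protein_meta` (protein_id,
#'   species, excluded), and `truth` (planted effects, collinear block ids,
#'   batch-effect table, latent group means, outlier cells).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_s <- sum(config$n_per_group)
  n_p <- config$n_proteins

  group <- rep(c("G1", "G2", "G3"), config$n_per_group)
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  # round-robin batch assignment within group keeps batches balanced
  batch <- unlist(lapply(config$n_per_group, function(n) {
    ((seq_len(n) - 1L) %% config$n_batches) + 1L
  }))
  sample_meta <- data.frame(
    sample_id = sample_ids, group = group, batch = as.integer(batch),
    stringsAsFactors = FALSE
  )

  protein_ids <- sprintf("P%04d", seq_len(n_p))
  da_idx <- if (config$n_da > 0L) seq_len(config$n_da) else integer(0)
  block_idx <- if (config$collinear_block_size > 0L) {
    config$n_da + seq_len(config$collinear_block_size)
  } else integer(0)

  # Base log2 signal: broad protein-location hyperprior, heavy right tail on
  # the raw scale; per-protein biological noise.
  mu <- stats::rnorm(n_p, mean = 20, sd = 2.5)
  sigma <- stats::runif(n_p, 0.6, 1.4)
  L <- matrix(stats::rnorm(n_p * n_s), n_p, n_s) * sigma + mu

  # Collinear block: hemoglobin-like, i.e. drawn at the top of the abundance
  # distribution (blood proteins dominate FIT-positive stool and are almost
  # always quantified) and driven by a shared latent factor; within-block
  # correlation lambda^2 / (lambda^2 + tau^2) = rho.
  if (length(block_idx) > 0) {
    mu[block_idx] <- stats::rnorm(length(block_idx), mean = 24.5, sd = 0.3)
    lambda <- 2.2
    tau <- lambda * sqrt((1 - config$collinear_rho) / config$collinear_rho)
    z <- stats::rnorm(n_s)
    for (i in block_idx) {
      L[i, ] <- mu[i] + lambda * z + tau * stats::rnorm(n_s)
    }
  }

  # Planted group effects (log2 shifts); G2 a configured fraction of G3.
  shift <- matrix(0, n_p, n_s)
  g2 <- group == "G2"
  g3 <- group == "G3"
  if (length(da_idx) > 0) {
    for (k in seq_along(da_idx)) {
      i <- da_idx[k]
      shift[i, g3] <- config$effect_sizes[k]
      shift[i, g2] <- config$g2_fraction * config$effect_sizes[k]
    }
  }
  if (length(block_idx) > 0) {
    shift[block_idx, g3] <- shift[block_idx, g3] + config$block_effect
    shift[block_idx, g2] <- shift[block_idx, g2] +
      config$g2_fraction * config$block_effect
  }
  # Noiseless latent group means (for exact planted-effect recovery tests).
  eff3 <- numeric(n_p)
  eff3[da_idx] <- config$effect_sizes
  eff3[block_idx] <- eff3[block_idx] + config$block_effect
  latent_means <- list(G1 = mu, G2 = mu + config$g2_fraction * eff3,
                       G3 = mu + eff3)
  L <- L + shift

  # Batch location/scale effects on ~batch_affected_fraction of proteins.
  # Block members are treated as one unit sharing a single batch effect:
  # protein groups built from the same subunits see the same peptides, so
  # their technical batch response is common, not independent.
  n_aff <- round(config$batch_affected_fraction * n_p)
  aff_idx <- if (n_aff > 0) sort(sample.int(n_p, n_aff)) else integer(0)
  block_affected <- any(block_idx %in% aff_idx)
  aff_idx <- setdiff(aff_idx, block_idx)
  batch_tab <- NULL
  if (length(aff_idx) > 0) {
    sh <- matrix(stats::rnorm(length(aff_idx) * config$n_batches,
                              sd = config$batch_shift_sd),
                 length(aff_idx), config$n_batches)
    sc <- matrix(exp(stats::rnorm(length(aff_idx) * config$n_batches,
                                  sd = config$batch_scale_sd)),
                 length(aff_idx), config$n_batches)
    # centre so batch effects do not change the overall protein mean
    sh <- sh - rowMeans(sh)
    for (j in seq_along(aff_idx)) {
      i <- aff_idx[j]
      for (b in seq_len(config$n_batches)) {
        s <- batch == b
        L[i, s] <- (L[i, s] - mean(L[i, ])) * sc[j, b] + mean(L[i, ]) + sh[j, b]
      }
    }
    batch_tab <- data.frame(
      protein_id = rep(protein_ids[aff_idx], each = config$n_batches),
      batch = rep(seq_len(config$n_batches), length(aff_idx)),
      shift = as.vector(t(sh)), scale = as.vector(t(sc))
    )
  }
  if (block_affected && length(block_idx) > 0) {
    shb <- stats::rnorm(config$n_batches, sd = config$batch_shift_sd)
    shb <- shb - mean(shb)
    scb <- exp(stats::rnorm(config$n_batches, sd = config$batch_scale_sd))
    for (i in block_idx) {
      for (b in seq_len(config$n_batches)) {
        s <- batch == b
        L[i, s] <- (L[i, s] - mean(L[i, ])) * scb[b] + mean(L[i, ]) + shb[b]
      }
    }
    batch_tab <- rbind(batch_tab, data.frame(
      protein_id = rep(protein_ids[block_idx], each = config$n_batches),
      batch = rep(seq_len(config$n_batches), length(block_idx)),
      shift = rep(shb, length(block_idx)), scale = rep(scb, length(block_idx))
    ))
  }

  # Gross outliers: +/- 6 log2 units on a few random cells. A hit on a block
  # protein is applied to the whole block in that sample: near-duplicate
  # protein groups quantify the same spectra, so interference spikes are
  # common to them, exactly like batch effects above.
  n_out <- round(config$outlier_rate * n_p * n_s)
  outlier_cells <- NULL
  if (n_out > 0) {
    cells <- sample.int(n_p * n_s, n_out)
    pr <- ((cells - 1L) %% n_p) + 1L
    sa <- ((cells - 1L) %/% n_p) + 1L
    dir <- sample(c(-6, 6), n_out, replace = TRUE)
    hit_block <- pr %in% block_idx
    for (j in which(hit_block)) {
      L[block_idx, sa[j]] <- L[block_idx, sa[j]] + dir[j]
    }
    pr_all <- c(pr[!hit_block],
                rep(block_idx, times = sum(hit_block)))
    sa_all <- c(sa[!hit_block],
                rep(sa[hit_block], each = length(block_idx)))
    dir_all <- c(dir[!hit_block],
                 rep(dir[hit_block], each = length(block_idx)))
    L[cbind(pr[!hit_block], sa[!hit_block])] <-
      L[cbind(pr[!hit_block], sa[!hit_block])] + dir[!hit_block]
    outlier_cells <- data.frame(
      protein_id = protein_ids[pr_all], sample_id = sample_ids[sa_all],
      shift = dir_all
    )
  }

  values <- 2^L
  dimnames(values) <- list(protein_ids, sample_ids)

  protein_meta <- data.frame(
    protein_id = protein_ids,
    species = sample(c("human", "human+dietary", "nonhuman"), n_p,
                     replace = TRUE, prob = c(0.92, 0.08, 0)),
    excluded = FALSE,
    stringsAsFactors = FALSE
  )

  truth <- list(
    da_protein_ids = protein_ids[da_idx],
    da_effects = stats::setNames(config$effect_sizes, protein_ids[da_idx]),
    collinear_block_ids = protein_ids[block_idx],
    batch_effect_table = batch_tab,
    latent_group_means = latent_means,
    outlier_cells = outlier_cells
  )

  list(
    matrix = abundance_matrix(values, scale_state = "raw"),
    sample_meta = sample_meta,
    protein_meta = protein_meta,
    truth = truth
  )
}

#' Inject (possibly abundance-dependent) missingness
#'
#' Masks cells of a fully observed raw matrix so that the realized missing
#' fraction lands within +/-2% of the target. The per-cell missingness
#' probability is Bernoulli with logit linear in the *row-centred* log2
#' intensity scaled by `mnar_weight`: low-abundance cells of a protein are
#' preferentially masked (MNAR) while per-protein missingness rates stay close
#' to the overall target, mirroring a post-filter LFQ matrix. On top of that,
#' the most abundant proteins are protected: the logit decreases with the
#' protein's mean log2 intensity above the matrix average (one-sided, so
#' low-abundance proteins stay near the overall rate and are not pushed below
#' the downstream 50% quantification filter). Dominant proteins — hemoglobins
#' in FIT-positive stool — are thus quantified nearly everywhere, as in the
#' real matrices. The intercept is calibrated numerically so the expected
#' missing fraction equals the target.
#'
#' @param matrix an [abundance_matrix()] with no missing cells (raw state).
#' @param missing_rate_target overall fraction of cells to mask, in \[0, 1).
#' @param mnar_weight in \[0,1\]: 0 gives missing-completely-at-random, 1 the
#'   strongest abundance dependence.
#' @param seed integer seed.
#' @return The matrix with masked cells set to `NA` and the mask updated.
#' @export
inject_missingness <- function(matrix, missing_rate_target, mnar_weight = 0.5,
                               seed = 1L) {
  check_state(matrix, "raw", "inject_missingness")
  if (any(!matrix$mask)) stop("matrix must be fully observed")
  if (missing_rate_target >= 1) stop("missing_rate_target must be < 1")
  if (missing_rate_target < 0) stop("missing_rate_target must be >= 0")
  if (missing_rate_target == 0) return(matrix)

  L <- log2(matrix$values)
  rm_ <- rowMeans(L)
  Lc <- L - rm_                         # row-centred abundance
  sd_all <- stats::sd(as.vector(Lc))
  slope <- if (sd_all > 0) 1.5 * mnar_weight / sd_all else 0
  # one-sided protection of the most abundant proteins
  sd_mu <- stats::sd(rm_)
  prot <- if (sd_mu > 0) {
    6 * mnar_weight * pmax((rm_ - mean(rm_)) / sd_mu, 0)
  } else 0
  lin <- -slope * Lc - prot
  # calibrate intercept: mean plogis(a + lin) = target
  f <- function(a) mean(stats::plogis(a + lin)) - missing_rate_target
  a <- stats::uniroot(f, c(-30, 30))$root
  p_miss <- stats::plogis(a + lin)

  set.seed(seed)
  miss <- matrix(stats::runif(length(L)) < p_miss, nrow(L), ncol(L))
  values <- matrix$values
  values[miss] <- NA_real_
  update_matrix(matrix, values, "raw", mask = !miss)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `abundance.tsv` (rows = protein groups, empty cell = missing),
#' `samples.tsv`, `proteins.tsv` and `truth.json` under `out_dir`.
#'
#' @param cohort result of [generate_cohort()] (optionally after
#'   [inject_missingness()] on its `$matrix`).
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- cohort$matrix$values
  df <- data.frame(protein_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, file.path(out_dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$sample_meta, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$protein_meta, file.path(out_dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
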