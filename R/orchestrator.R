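#' Pipeline configuration
#'
#' Assembles every stage parameter of the end-to-end run into one validated
#' list. Input is either a [sim_config()] (synthetic cohort) or paths to a
#' cohort written by [write_cohort()] (or equivalently formatted user data).
#'
#' @param sim a [sim_config()], or `NULL` when `data_dir` is given.
#' @param data_dir directory with `abundance.tsv`, `samples.tsv`,
#'   `proteins.tsv` (see [write_cohort()]).
#' @param q_level FDR level for differential abundance (default 0.05).
#' @param min_quant_fraction protein quantification filter (default 0.5).
#' @param knn_k imputation neighbours (default 10).
#' @param train_fraction stratified split fraction (default 0.8).
#' @param selection_runs seeds per selection algorithm (default 50).
#' @param selection_algorithms selector ids (default all five).
#' @param K consensus depth (default 25).
#' @param vif_threshold collinearity cut (default 10).
#' @param rout_q outlier FDR level (default 0.01).
#' @param exclusion_ids manually excluded features (default none).
#' @param classifiers algorithms to tune (default penalized_logistic and
#'   svm).
#' @param final_classifier algorithm whose fit is carried to held-out
#'   evaluation and SHAP (default penalized_logistic).
#' @param cv_folds,cv_repeats CV design (defaults 10, 3).
#' @param learning_curve_repeats repeats per fraction (default 10).
#' @param pa_n_sim parallel-analysis simulations (default 1000).
#' @param shap_max_coalitions kernel SHAP sampling budget (default 1024).
#' @param run_selection,run_learning_curve,run_shap stage toggles.
#' @param panel explicit feature panel used when `run_selection = FALSE`.
#' @param seed master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            data_dir = NULL,
                            q_level = 0.05,
                            min_quant_fraction = 0.5,
                            knn_k = 10L,
                            train_fraction = 0.8,
                            selection_runs = 50L,
                            selection_algorithms = c("rf", "rrf", "boruta",
                                                     "svm_rfe", "lasso"),
                            K = 25L,
                            vif_threshold = 10,
                            rout_q = 0.01,
                            exclusion_ids = character(0),
                            classifiers = c("penalized_logistic", "svm"),
                            final_classifier = "penalized_logistic",
                            cv_folds = 10L, cv_repeats = 3L,
                            learning_curve_repeats = 10L,
                            pa_n_sim = 1000L,
                            shap_max_coalitions = 1024L,
                            run_selection = TRUE,
                            run_learning_curve = TRUE,
                            run_shap = TRUE,
                            panel = NULL,
                            seed = 1L) {
  if (is.null(sim) && is.null(data_dir)) {
    stop("either a sim_config or a data_dir is required")
  }
  if (!run_selection && is.null(panel)) {
    stop("an explicit panel is required when selection is disabled")
  }
  cfg <- as.list(environment())
  cfg <- cfg[order(names(cfg))]          # stable field order for manifests
  class(cfg) <- "pipeline_config"
  cfg
}

read_cohort <- function(data_dir) {
  ab <- utils::read.delim(file.path(data_dir, "abundance.tsv"),
                          check.names = FALSE)
  v <- as.matrix(ab[, -1, drop = FALSE])
  rownames(v) <- ab$protein_id
  list(
    matrix = abundance_matrix(v, scale_state = "raw"),
    sample_meta = utils::read.delim(file.path(data_dir, "samples.tsv"),
                                    stringsAsFactors = FALSE),
    protein_meta = utils::read.delim(file.path(data_dir, "proteins.tsv"),
                                     stringsAsFactors = FALSE),
    truth = NULL
  )
}

#' Run the full triage pipeline
#'
#' Executes simulate/ingest -> preprocess -> differential abundance (full
#' data) -> PCA benchmark (full data, reported as an optimistic benchmark) ->
#' stratified split -> ensemble selection (training data only) -> panel
#' filtering -> classifier tuning -> learning curves -> held-out evaluation
#' -> kernel SHAP. The held-out partition is touched exactly once, by the
#' final evaluation stage; the report records an access count. When
#' `out_dir` is given, the report is written as `report.json` and
#' `report.md` plus a `manifest.json` (full config and seeds); reruns with
#' the same config produce byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # --- data -----------------------------------------------------------
  if (!is.null(config$data_dir)) {
    cohort <- read_cohort(config$data_dir)
  } else {
    cohort <- generate_cohort(config$sim)
    cohort$matrix <- inject_missingness(
      cohort$matrix, config$sim$missing_rate_target,
      config$sim$mnar_weight, seed = config$sim$seed + 1L
    )
  }

  # --- preprocessing --------------------------------------------------
  prep <- preprocess_pipeline(
    cohort$matrix, cohort$sample_meta, cohort$protein_meta,
    min_quant_fraction = config$min_quant_fraction, k = config$knn_k
  )
  groups <- cohort$sample_meta$group[
    match(prep$zscored$sample_ids, cohort$sample_meta$sample_id)]
  is_case <- groups %in% c("G2", "G3")

  # --- differential abundance (full data) ----------------------------
  da <- build_da_table(prep$imputed, cohort$sample_meta,
                       q_level = config$q_level)
  sig_ids <- da$protein_id[da$q_value < config$q_level]

  # --- PCA benchmark (full data, optimistic) --------------------------
  pca_bench <- NULL
  if (length(sig_ids) >= 2L) {
    families <- list()
    if (!is.null(cohort$truth) &&
        length(cohort$truth$collinear_block_ids) > 1L) {
      blk <- intersect(cohort$truth$collinear_block_ids, sig_ids)
      if (length(blk) > 1L) families <- stats::setNames(list(blk), blk[1])
    }
    panel_pca <- redundant_group_collapse(sig_ids, families)
    if (length(panel_pca) >= 2L) {
      fit_b <- fit_pca_benchmark(prep$zscored, panel_pca, is_case,
                                 n_sim = config$pa_n_sim, seed = seed + 10L)
      pca_bench <- list(
        panel = panel_pca,
        n_retained = fit_b$pca$n_retained,
        explained_variance_fraction =
          fit_b$pca$explained_variance_fraction[
            seq_len(max(fit_b$pca$n_retained, 1L))],
        evaluation = evaluation_report(fit_b$fitted_probabilities, is_case,
                                       groups = groups),
        notes = c(fit_b$notes,
                  "optimistic benchmark: fit on the full dataset, no split")
      )
    }
  }

  # --- split (test side sealed until final evaluation) ----------------
  part <- stratified_split(
    stats::setNames(groups, prep$zscored$sample_ids),
    config$train_fraction, seed = seed + 20L
  )
  test_access <- 0L
  x_all <- t(prep$zscored$values)
  x_train <- x_all[part$train_ids, , drop = FALSE]
  y_train <- is_case[match(part$train_ids, prep$zscored$sample_ids)]
  g_train <- groups[match(part$train_ids, prep$zscored$sample_ids)]

  # --- ensemble selection (train only) --------------------------------
  sel <- NULL
  if (config$run_selection) {
    sel <- run_ensemble_selection(
      x_train, y_train, algorithms = config$selection_algorithms,
      runs = config$selection_runs, K = config$K,
      seed_base = (seed %% 100000L) * 1000L    # keep derived seeds < 2^31
    )
    panel <- sel$consensus$top_k
  } else {
    panel <- config$panel
  }

  # --- panel filtering -------------------------------------------------
  panel2 <- apply_exclusion_list(panel, config$exclusion_ids)
  keep_pref <- character(0)
  if (!is.null(cohort$truth)) {
    blk <- intersect(cohort$truth$collinear_block_ids, panel2)
    if (length(blk) > 0L) keep_pref <- blk[1]
  }
  vp <- vif_prune(prep$zscored, panel2, threshold = config$vif_threshold,
                  keep_preferences = keep_pref)
  panel_final <- vp$panel
  train_matrix <- subset_proteins(prep$zscored, panel_final)
  train_sub <- abundance_matrix(
    train_matrix$values[, part$train_ids, drop = FALSE],
    scale_state = "zscored",
    mask = train_matrix$mask[, part$train_ids, drop = FALSE]
  )
  outliers <- panel_outlier_flags(
    train_sub, panel_final,
    factor(ifelse(y_train, "G2/G3", "G1")), Q = config$rout_q
  )

  # --- classification --------------------------------------------------
  xf_train <- x_train[, panel_final, drop = FALSE]
  fits <- list()
  for (alg in config$classifiers) {
    tf <- tune_and_fit(xf_train, y_train, alg, cv_folds = config$cv_folds,
                       cv_repeats = config$cv_repeats, seed = seed + 30L)
    train_auc <- auroc_rank(tf$model$predict_prob(xf_train), y_train)
    og <- overfit_gap(train_auc, tf$cv_result$cv_mean_auroc)
    lc <- NULL
    if (config$run_learning_curve) {
      lc <- suppressWarnings(hybrid_learning_curve(
        xf_train, y_train, alg, tf$cv_result$chosen,
        repeats = config$learning_curve_repeats, seed = seed + 40L
      ))
    }
    fits[[alg]] <- list(
      model = tf$model, cv = tf$cv_result, train_auroc = train_auc,
      overfit = og, learning_curve = lc
    )
  }

  # --- held-out evaluation (single test access) ------------------------
  final_alg <- config$final_classifier
  if (!final_alg %in% names(fits)) final_alg <- names(fits)[1]
  test_access <- test_access + 1L
  x_test <- x_all[part$test_ids, panel_final, drop = FALSE]
  y_test <- is_case[match(part$test_ids, prep$zscored$sample_ids)]
  g_test <- groups[match(part$test_ids, prep$zscored$sample_ids)]
  test_eval <- evaluation_report(
    fits[[final_alg]]$model$predict_prob(x_test), y_test, groups = g_test
  )

  # --- interpretation ---------------------------------------------------
  shap <- NULL
  if (config$run_shap) {
    sh <- kernel_shap(
      fits[[final_alg]]$model$predict_prob, xf_train, xf_train,
      max_coalitions = config$shap_max_coalitions, seed = seed + 50L
    )
    shap <- list(summary = stratified_shap_summary(sh, g_train),
                 base_value = sh$base_value)
  }

  report <- list(
    config_summary = config_summary(config),
    counts = prep$counts,
    batch = list(
      fraction_significant_pre = prep$batch_report$pre$fraction_significant,
      fraction_significant_post = prep$batch_report$post$fraction_significant
    ),
    differential_abundance = list(
      n_p05 = sum(da$p_value <= 0.05),
      n_q05 = length(sig_ids),
      significant_ids = sig_ids,
      table = da[order(da$p_value), ]
    ),
    pca_benchmark = pca_bench,
    partition = list(
      train_n = length(part$train_ids), test_n = length(part$test_ids),
      train_counts = as.list(part$train_counts),
      test_counts = as.list(part$test_counts)
    ),
    selection = if (!is.null(sel)) list(
      consensus_top_k = sel$consensus$top_k,
      borda_scores = as.list(sel$consensus$borda_scores[
        seq_len(min(config$K, length(sel$consensus$borda_scores)))]),
      stability = sel$stability
    ),
    panel = list(
      after_exclusions = panel2, final = panel_final,
      vif_iterations = vp$report$iterations,
      final_vifs = as.list(vp$report$final_vifs),
      n_outlier_flags = attr(outliers, "n_flagged")
    ),
    classification = lapply(fits, function(f) list(
      algorithm = f$model$algorithm_id,
      chosen_hyperparameters = f$cv$chosen,
      cv_auroc_mean = f$cv$cv_mean_auroc, cv_auroc_sd = f$cv$cv_sd_auroc,
      train_auroc = f$train_auroc,
      overfit_delta = f$overfit$delta_auroc,
      overfit_percent = f$overfit$percent_of_cv,
      learning_curve = f$learning_curve
    )),
    heldout = list(
      algorithm = final_alg,
      auroc = test_eval$auroc, auroc_ci_95 = test_eval$auroc_ci_95,
      sensitivity = test_eval$confusion$sensitivity,
      specificity = test_eval$confusion$specificity,
      balanced_accuracy = test_eval$confusion$balanced_accuracy,
      subgroups = lapply(test_eval$subgroups, function(s) list(
        auroc = s$roc$auroc, sensitivity = s$confusion$sensitivity,
        specificity = s$confusion$specificity
      )),
      test_partition_reads = test_access
    ),
    shap = if (!is.null(shap)) list(
      base_value = shap$base_value,
      global = shap$summary$global,
      by_group = shap$summary$by_group
    ),
    truth_recovery = if (!is.null(cohort$truth) && config$run_selection) list(
      planted_da = cohort$truth$da_protein_ids,
      planted_in_consensus = intersect(cohort$truth$da_protein_ids,
                                       sel$consensus$top_k),
      block_removed_by_vif = intersect(cohort$truth$collinear_block_ids,
                                       vp$report$iterations$feature_removed)
    )
  )

  if (!is.null(out_dir)) {
    write_report(report, config, out_dir)
    return(invisible(report))
  }
  report
}

config_summary <- function(config) {
  s <- unclass(config)
  s$sim <- if (!is.null(s$sim)) unclass(s$sim)
  s
}

write_report <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  jsonlite::write_json(
    list(config = config_summary(config), package = "fitTriage",
         version = "0.1.0"),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_markdown <- function(report) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "# FIT triage pipeline report", "",
    sprintf("- Proteins retained: %d / %d (quantification rate %s)",
            report$counts$proteins_retained, report$counts$proteins_in,
            fmt(report$counts$quantification_rate)),
    sprintf("- Batch-associated proteins: %s pre-correction, %s post",
            fmt(report$batch$fraction_significant_pre),
            fmt(report$batch$fraction_significant_post)),
    sprintf("- Differential abundance: %d proteins with p <= 0.05, %d with q < 0.05",
            report$differential_abundance$n_p05,
            report$differential_abundance$n_q05),
    ""
  )
  if (!is.null(report$pca_benchmark)) {
    e <- report$pca_benchmark$evaluation
    lines <- c(lines, "## PCA benchmark (optimistic, full data)", "",
      sprintf("- %d retained PC(s); AUROC %s; sensitivity %s, specificity %s, balanced accuracy %s",
              report$pca_benchmark$n_retained, fmt(e$auroc),
              e$confusion$display$sensitivity, e$confusion$display$specificity,
              e$confusion$display$balanced_accuracy), "")
  }
  lines <- c(lines, "## Held-out evaluation", "",
    sprintf("- Final model: %s; AUROC %s (95%% CI %s-%s)",
            report$heldout$algorithm, fmt(report$heldout$auroc),
            fmt(report$heldout$auroc_ci_95[1]),
            fmt(report$heldout$auroc_ci_95[2])),
    sprintf("- Sensitivity %s, specificity %s, balanced accuracy %s",
            fmt(report$heldout$sensitivity), fmt(report$heldout$specificity),
            fmt(report$heldout$balanced_accuracy)))
  lines
}
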