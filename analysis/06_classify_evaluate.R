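#!/usr/bin/env Rscript
# Downstream of selection: VIF-based panel filtering with the block
# representative protected, ROUT outlier flags, hyperparameter tuning of the
# penalized-logistic and SVM classifiers by 10-fold x 3 repeated stratified
# CV (AUROC-optimized), overfitting diagnostics, hybrid learning curves,
# held-out evaluation of the final model, and kernel SHAP attributions.
# This is the full pipeline; it reuses run_pipeline() so every number here
# is reproducible from one seed.

suppressPackageStartupMessages(library(fitTriage))

cfg <- pipeline_config(
  sim = sim_config(),
  selection_runs = 50L,
  classifiers = c("penalized_logistic", "svm"),
  final_classifier = "penalized_logistic",
  seed = 1L
)
report <- run_pipeline(cfg, out_dir = "results/run")

cat(sprintf("final panel (%d features): %s\n", length(report$panel$final),
            paste(report$panel$final, collapse = " ")))
for (alg in names(report$classification)) {
  c <- report$classification[[alg]]
  cat(sprintf("%s: CV AUROC %.3f +/- %.3f, train %.3f, overfit %.3f (%.1f%%)\n",
              alg, c$cv_auroc_mean, c$cv_auroc_sd, c$train_auroc,
              c$overfit_delta, c$overfit_percent))
}
cat(sprintf("held-out (%s): AUROC %.3f (95%% CI %.3f-%.3f), sens %.3f, spec %.3f\n",
            report$heldout$algorithm, report$heldout$auroc,
            report$heldout$auroc_ci_95[1], report$heldout$auroc_ci_95[2],
            report$heldout$sensitivity, report$heldout$specificity))
cat("top features by mean |SHAP|:\n")
print(head(report$shap$global, 5))
cat("full report written to results/run/\n")
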