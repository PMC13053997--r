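Package: fitTriage
Title: Triage of FIT-Positive Colorectal Cancer Screening Samples from Stool Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for triaging fecal-immunochemical-test (FIT)
    positive colorectal-cancer screening samples (false positives versus advanced
    adenoma or carcinoma) from a label-free stool-proteomics abundance matrix.
    Implements matrix filtering and a five-step preprocessing pipeline (log2,
    quantile normalization, empirical-Bayes batch correction, k-nearest-neighbour
    imputation, z-scaling), Mann-Whitney differential abundance with the
    Benjamini-Krieger-Yekutieli two-stage adaptive FDR, a PCA benchmark classifier
    with Monte-Carlo parallel analysis, multi-seed multi-algorithm Borda-consensus
    feature selection with stability curves, variance-inflation and robust-outlier
    panel filtering, supervised classifiers tuned by repeated stratified
    cross-validation with overfitting diagnostics and hybrid learning curves,
    held-out evaluation with DeLong confidence intervals, and kernel SHAP model
    interpretation. A synthetic-cohort generator with planted ground truth makes
    every stage testable without the original mass-spectrometry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    xgboost,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
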