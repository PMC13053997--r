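---
title: "Methods: triaging FIT-positive screening samples from stool proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triaging FIT-positive screening samples from stool proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A positive fecal immunochemical test (FIT) triggers a colonoscopy referral,
but roughly half of FIT-positive individuals show no lesion at colonoscopy.
`fitTriage` implements an analysis pipeline that asks whether label-free
quantitative (LFQ) proteomics on the *leftover* FIT sample can triage these
referrals: separating false positives (G1) from advanced adenomas (G2) and
carcinomas (G3). The pipeline takes a protein-group x sample intensity
matrix with sample metadata (diagnostic group, acquisition batch) and
protein metadata (species inference, manual-review exclusions), and runs
preprocessing, rank-based differential abundance, a PCA benchmark
classifier, consensus feature selection, panel filtering, supervised
classification with overfitting diagnostics, and model interpretation.

Because the deposited mass-spectrometry data are not required here, a
synthetic-cohort generator reproduces the statistical structure the
downstream stages assume, with planted ground truth so every stage can be
tested for *recovery*, not just for running.

## The synthetic cohort: what it emulates and what it does not

`sim_config()` defaults encode the study conditions: 141 samples
(50 G1 / 45 G2 / 46 G3) in four balanced batches (round-robin within group),
334 retained protein groups, and an overall quantification rate of 78%.
On top of a per-protein log-normal base signal (log2 locations from a broad
`N(20, 2.5)` hyperprior, per-protein noise SD uniform on 0.6-1.4):

* **Planted differential proteins.** 15 proteins carry signed log2 shifts in
  cases; defaults are 9 up / 6 down with magnitudes 1.2-2.0 in G3 and 60% of
  that in G2, reflecting the more subtle alterations of adenomas. Real
  per-protein effect sizes and variance structure are not identifiable from
  published summary statistics, so these magnitudes are documented
  placeholders chosen to yield strong but not trivial recovery at n = 141.
* **A hemoglobin-like collinear block.** Five proteins driven by one latent
  factor (target pairwise correlation 0.995) with a shared +1.4 log2 case
  shift. The block is drawn at the top of the abundance distribution
  (`mu ~ N(24.5, 0.3)`) with a large latent SD (2.2): in FIT-positive stool,
  hemoglobin is the dominant analyte, varies over orders of magnitude, and is
  quantified essentially everywhere. Because such blocks are near-duplicate
  protein groups sharing subunits (and hence spectra), batch effects and
  gross-outlier hits are applied *jointly* to the block, not independently
  per member — this is what lets the processed data retain the block's
  multicollinearity (VIF >= 10), as observed in real matrices.
* **Batch effects.** 25% of proteins get per-batch location shifts
  (SD 0.8 log2 units, centred) and scale factors (log-SD 0.15).
* **Missingness.** Cell-wise Bernoulli with logit linear in the row-centred
  log2 intensity (slope `1.5 * mnar_weight` per within-protein SD), plus a
  one-sided protection term (`6 * mnar_weight` per SD of protein mean
  abundance above the matrix average). The within-protein term produces
  abundance-dependent (MNAR) missingness; the one-sided between-protein term
  keeps the most abundant proteins near-completely quantified without
  pushing low-abundance proteins below the 50% filter — the generator
  emulates a *post-filter* matrix, in which the worst proteins are already
  gone. The intercept is calibrated numerically so the realized rate hits
  the target within ±2%.
* **Gross outliers.** A fraction (default 0.002) of cells shifted ±6 log2
  units.

What the generator does **not** emulate: peptide-level structure, shared
missingness patterns between correlated non-block proteins, non-Gaussian
(e.g. bimodal) biology, microbiome composition, or any real inter-protein
correlation network beyond the single planted block. Passing recovery tests
on this cohort therefore demonstrates that the pipeline's machinery is
correct and calibrated — not that the biological signal in any real cohort
is as clean.

## Preprocessing

The pipeline order is fixed and enforced through a `scale_state` tag:
filter → log2 → quantile normalization → batch correction → KNN imputation
→ z-scaling. Operations refuse out-of-order input.

* **Filtering** keeps proteins quantified in ≥ 50% of samples (boundary
  inclusive) that are human-exclusive or human co-inferred with a dietary
  species, and honours a manual exclusion flag.
* **Quantile normalization** runs *before* imputation, so it must tolerate
  missing cells: observed values in each column are ranked among themselves
  and projected onto the across-column mean quantile curve by linear
  interpolation (ties get the average of their target quantiles). On
  complete matrices this reduces to the standard algorithm (and is checked
  against `limma::normalizeQuantiles`). Treating missing cells as zeros is
  the main alternative; it was rejected because downstream imputation would
  then inherit normalization artifacts at the bottom of each column.
* **Batch assessment** is a per-protein one-way F-test on observed cells,
  reported descriptively as the fraction with p < 0.05 (about 25% on the
  default cohort pre-correction, ~5% under permuted labels). A protein with
  any batch containing fewer than two observed cells is flagged `NA`, not
  dropped.
* **Batch correction** is a parametric empirical-Bayes location/scale
  adjustment (standardize per protein against a batch-design fit and pooled
  variance; shrink per-batch per-protein means toward a normal prior and
  variances toward a moment-matched inverse-gamma prior by iterating the
  posterior-mean equations; adjust and restore). It is implemented
  in-package so that missing cells pass through untouched, and is checked
  against `sva::ComBat` on complete matrices. Diagnostic group is *not*
  protected as a covariate; a warning notes that confounded group signal
  may be removed. Batches of size one are rejected (variance inestimable).
* **KNN imputation** (k = 10) fills a missing cell with the protein's mean
  over the k nearest samples; sample distances are Euclidean over mutually
  observed proteins, divided by the square root of the observed fraction so
  sparse overlaps are not spuriously close. A sample sharing no proteins
  with any other falls back to the protein mean (logged). Observed cells
  are never altered and the original mask is kept for provenance.
* **Z-scaling** uses the population (1/n) SD — the choice is irrelevant
  downstream but fixed for reproducibility; zero-variance proteins are an
  error naming the offenders.

## Differential abundance

Per protein, a two-sided Mann-Whitney U test compares pooled cases (G2+G3)
against G1: exact enumeration for combined n ≤ 12 without ties, otherwise
the normal approximation with tie and continuity corrections. Because
z-scaling is monotone per protein, p-values are identical on the imputed and
z-scored matrices; fold changes are only meaningful pre-z-score, so
`build_da_table()` is run on the imputed (log2) matrix and reports the
difference of group means as the log2 fold change.

Multiplicity is handled by the Benjamini–Krieger–Yekutieli two-stage
step-up procedure: BH at q' = q/(1+q), estimate the null count from stage-1
rejections, rerun BH at the inflated level. BKY is defined as a rejection
procedure, not a q-value formula; per-protein q-values are defined
operationally as the smallest nominal level at which the procedure rejects
that protein, found by bisection to 1e-6. Under the global null the
procedure's false-discovery proportion is verified ≤ 0.07 at q = 0.05 over
200 simulated 334-protein null cohorts.

## PCA benchmark

PCA (SVD of the column-centred z-scored panel; loading signs fixed so the
largest-magnitude element is positive) with Monte-Carlo parallel analysis:
a PC is retained while its eigenvalue exceeds the 95th percentile of the
corresponding eigenvalues from standard-normal matrices of the same shape
(default 1000 simulations; the data are z-scored, so correlation and
covariance eigenvalues coincide). Logistic regression on the retained PC
scores gives class probabilities. The benchmark is deliberately fit on the
full dataset with no split — its metrics are labelled an *optimistic
benchmark*. On separation (or zero retained PCs) the fit falls back to a
tiny-ridge (1e-8) or intercept-only model so results stay deterministic.
Known collinear families (the hemoglobin block) are collapsed to a
designated representative *before* PCA, since the assay itself already
measures hemoglobin; the family map is an explicit input.

## Ensemble feature selection

Five selectors run under one contract (full importance vector,
deterministic tie-break) on the training partition only: random-forest
permutation importance (`ranger`), a regularized random forest (`ranger`
with a 0.8 regularization factor penalizing feature re-use), an in-package
Boruta (shadow-feature permutation test with binomial confirm/reject
decisions, ≤ 100 iterations with early stopping, decided features dropped
from later iterations), SVM-RFE with a radial kernel (the RBF kernel
factorizes over features, so the signed change in the fitted margin term
when a feature is dropped is computed exactly; 20% of features are
eliminated per step above 40 features, then one at a time), and an L1
logistic path scored by |coefficient| at the CV-chosen penalty (`glmnet`).
"Modified model" variants (confirmed-only Boruta; bootstrap resampling for
RRF, lasso and SVM-RFE) are available through per-algorithm options.

Each algorithm runs 50 times under different seeds; each run's top 25
features earn Borda points (K − rank + 1, zero beyond K = 25); per-algorithm
consensus lists are aggregated by the same truncated Borda scheme into the
final top-25 consensus. Ties break by mean rank, then feature id. Stability
is summarized as the mean pairwise Spearman correlation of top-k rankings
(k = 3..25) across the 50 runs, with features outside a run's top-k assigned
the tied rank k + 1 — pairwise Spearman needs complete rankings on the
union, and this convention penalizes disagreement without dominating it.

## Panel filtering

Manual spectral-review exclusions are an input list (set difference,
order-preserving, warning on unknown ids). Multicollinearity is pruned by
iterated VIF: regress each panel feature on the rest, VIF = 1/(1 − R²),
remove the worst unprotected feature at VIF ≥ 10, recompute; exact
collinearity yields VIF = ∞ and is removed first; protected representatives
(the hemoglobin stand-in) are never removed. An infinite threshold turns
the function into a pure VIF report. Outliers are flagged per feature
within each class by the cited robust outlier procedure in its
constant-model form: residuals from the median, robust scale from the
68.27th percentile of absolute residuals with an n/(n−1) small-n
correction, outermost-first t-tests against the stepped threshold
Q·i/n. The exact small-sample constants of the original software are
unpublished; this formula is the documented choice, Q stays exposed, and
flags are reported rather than auto-removed (the panel is expected to be
established "with minimal outlier impact", so removal policy is left to
the caller).

## Classification and evaluation

The 80/20 split is stratified on the three-level diagnostic group with
round-half-up per-class training counts — the unique rule reproducing a
113/28 split with test counts (10, 9, 9) from (50, 45, 46). Tuning uses
stratified 10-fold CV repeated 3 times, scored by AUROC (rank formulation,
half credit for ties), with ties between grid points broken toward the
later (more regularized) row. Default grids are conventional —
penalized logistic crosses mixing α ∈ {0, .25, .5, .75, 1} with 20
log-spaced penalties in [1e-4, 1]; these are conventional ranges, not a
reproduction of any specific published configuration — and all grids are
overridable.
Six wrappers share a probability contract: glmnet, ranger, xgboost,
k-nearest neighbours, polynomial-kernel SVM, naive Bayes.

Overfitting is reported as Δ = train AUROC − CV AUROC and 100·Δ/CV, with a
5% stability flag (withheld when CV AUROC ≤ 0.5). Hybrid learning curves
refit the tuned configuration on stratified subsamples (10-90% of the
training set, 10 repeats) and evaluate on the complement, reporting
mean ± SEM; fractions leaving a single-class side are skipped with a
warning. Held-out evaluation happens once, on the sealed 20% partition:
confusion metrics at the 0.5 threshold (stored full-precision; displayed
percentages round half-up), AUROC with a DeLong 95% CI, Youden-optimal
operating point (ties to the lowest threshold), and subgroup reports
(G2-only and G3-only vs G1). Correlated classifiers are compared by the
paired DeLong test with BH adjustment; both the variance estimator and the
test are implemented from the placement-value formulas and cross-checked
against `pROC`.

## Interpretation

Kernel SHAP in the weighted-least-squares formulation: coalition values are
marginal expectations over the training background; all 2^M − 2 coalitions
are enumerated for M ≤ 12 features, otherwise coalitions are sampled in
complementary pairs by kernel-weighted size (singletons and leave-one-out
always included, default budget 1024). The efficiency constraint is imposed
exactly in the solve, so per-sample attributions plus the base value equal
the model output in both modes. Explanations are computed on the
probability scale (the quantity a screening decision uses), for the
training samples against the training background; both are configurable.
Exactness is tested against brute-force Shapley enumeration, and the
linear-model closed form w_j(x_j − mean background) is recovered.

## Orchestration, determinism and problem sizes

`run_pipeline()` chains the stages (benchmark on full data; selection,
tuning and curves on the training side; one sealed read of the test side,
counted and reported) and writes `report.json`, `report.md` and a
`manifest.json` holding the full configuration. All randomness derives from
the config seeds, and reruns are byte-identical; the test suite asserts
this on a reduced configuration (4 selection seeds, 3 algorithms), while
the recovery tests run the full 50-seed, five-algorithm ensemble — twice,
with disjoint seed batches — on the default cohort. The acceptance script
performs one complete default-sized run (50 seeds per algorithm, 1000
parallel-analysis simulations, 10 learning-curve repeats), which takes
around ten minutes on one core.

## Known limitations

* The generator's effect sizes and variance structure are placeholders;
  absolute performance numbers on
  synthetic cohorts are not comparable to real-data performance.
* Quantile normalization under strong asymmetric differential abundance
  slightly distorts null proteins in the affected samples (a known property
  of the method, visible here as a mild excess of borderline discoveries on
  cohorts with many planted up-shifts).
* Batch correction without group protection can absorb group signal when
  batch and group are confounded; the balanced-batch design avoids this,
  and the warning stays on for user data.
* Nested cross-validation (tuning inside each fold) is out of scope; CV
  AUROCs are mildly optimistic, which is exactly what the overfit gap and
  learning curves are there to expose.
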