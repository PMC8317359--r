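---
title: "Methods: PET radiomics and IHC models of lymphovascular space invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics and IHC models of lymphovascular space invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lymphovascular space invasion (LVSI) — tumour cells inside lymphatic or
blood-vessel spaces — is a strong prognostic factor in early-stage
(FIGO Ia–IIa) cervical squamous cell carcinoma, but it can only be
confirmed on post-operative pathology. `radlvsi` implements a
non-invasive modelling pipeline that predicts LVSI from two
complementary sources: the spatial heterogeneity of FDG uptake in the
primary tumour on PET (summarised by a radiomics signature, the
*Rad-score*) and the immunohistochemical expression of tenascin-C
(TNC) and cyclooxygenase-2 (COX-2), two proteins linked to
lymphangiogenesis and stromal invasion.

Because no patient images are distributed with the package, a seeded
synthetic-data generator reproduces the *statistical structure* the
analysis assumes, so every stage runs, and is tested, end to end.

## PET segmentation and the feature catalogue

The tumour volume of interest (VOI) is segmented at a fixed threshold
of 42% of the global SUVmax, keeping the 26-connected component that
contains the hottest voxel (`segment_voi()`). From the VOI,
`extract_all()` produces exactly 401 features in six families
(`feature_catalog()`, shipped as versioned JSON):

* **5 conventional**: SUVmax, SUVmean, SUVpeak (mean in a 1-cm³ sphere
  on the hottest voxel, clipped to the grid), MTV (voxels × voxel
  volume) and TLG (SUVmean × MTV).
* **42 histogram**: first-order statistics of the in-mask SUVs. All
  quantiles use the linear-interpolation convention
  (`stats::quantile` type 7); entropy, uniformity and the mode use a
  64-bin equal-width histogram of the in-mask range; skewness and
  excess kurtosis of a zero-variance sample are reported as 0 with a
  warning. The roster includes the `Quantile0.025` term used by the
  published Rad-score and the 19 percentiles 5–95%.
* **144 co-occurrence (GLCM)** and **180 run-length (GLRLM)**: the SUVs
  are first quantized to Ng = 64 equal-width levels over the in-mask
  range (a constant region maps to level 1). Texture directions are
  the four in-plane axial angles (0°, 45°, 90°, 135°) applied
  slice-wise and pooled across slices *before* normalisation —
  in-plane and axial spacings differ on PET, and the feature names
  carry 2-D angle labels. Each base feature appears at offsets 1, 4
  and 7 voxels for each angle, plus an `AllDirection` mean and an
  `AllDirection..._SD` (population SD, divisor 4) over the four
  per-angle values. Run-length matrices have no pair offset; the
  offset token in GLRLM names is a direction-family label only, so the
  run-length values are identical across the three offset blocks.
* **21 zone-size (GLZSM)**: 26-connected zones of equal level. The two
  features named by the published model follow their printed
  definitions: HighIntensityLargeAreaEmphasis = ΣZ(g,s)·g²s²/N and
  LowIntensityEmphasis = Σ(Z/g²)/N.
* **9 form factor**: volume, face-counting surface area, their ratio,
  sphericity, two compactness variants, spherical disproportion,
  maximum 3-D diameter (over boundary-voxel centres) and eccentricity
  (from the voxel-coordinate covariance). Face counting measures the
  digital (staircase) surface; for a rasterised ball it converges to
  1.5× the smooth-sphere area, so the sphericity of a large digital
  ball tends to 2/3 rather than 1 — the tests freeze this limit.

Numerical edge cases are deliberate: a co-occurrence matrix with no
valid voxel pair at a direction/offset reports zeros with a warning,
and zero grey-level variance makes Correlation and
HaralickCorrelation undefined, so both return 0 with a warning. This
keeps constant-tumour fixtures finite and testable.

## Rad-score

Features are Z-score standardised with parameters fitted on the
training set only (sample SD, divisor n−1; zero-variance training
features are dropped with a warning). `lasso_select()` runs an
L1-penalised logistic path (glmnet) over 100 log-spaced penalties from
the analytic λ_max down four decades, picking the λ that minimises the
mean binomial deviance in seeded, outcome-stratified 10-fold
cross-validation — the selection rule of the original analysis, which
reported λ = 0.02 and 16 surviving features on its data. The selected
features and coefficients define the Rad-score
(`rad_score_model_from_selection()`, `rad_score()`).

The package also ships the published 16-coefficient PET Rad-score
(`published_radscore_model()`, intercept −0.075) keyed to catalogue
feature names; it is evaluated verbatim and protected by exact tests.
The pipeline always re-selects λ on its own data rather than reusing
the published operating point.

## Immunohistochemistry quantification

`classify_pixels()` colour-deconvolves RGB tiles with the standard
H-DAB stain vectors and classifies tissue pixels as strong, moderate
or weak DAB-positive or hematoxylin-negative; low-density pixels are
excluded as background and counts are conserved. The software whose
behaviour this emulates publishes only colour-word class definitions,
so the DAB density cuts default to equal thirds of the observed
positive-density range and are configurable. "Percentage of positive
cells" is approximated by the positive pixel-area fraction, the same
quantity the densitometric software reports; cell-level counting is
out of scope.

The H-score is the product of the intensity category (0–3; the
positive class with the largest area, ties toward the higher
intensity) and the percentage category (0: none, +1: <5%, +2: 5–20%,
+3: 21–50%, +4: >50%), giving the reachable values
{0, 1, 2, 3, 4, 6, 8, 9, 12}. Expression groups follow the printed
sets — negative/weak {1, 2}, moderate {3, 4, 6}, strong {8, 9, 12} —
with two boundary decisions: an H-score of 0 (left unassigned by the
printed sets) joins the negative/weak group, and unreachable values
fall to the nearest printed boundary below.

## Cohort handling and statistics

Eligibility filtering removes records flagged for prior
chemoradiotherapy, tumour volume < 1 cm³ or surgery elsewhere
(`apply_eligibility()`). The random 7:3 split uses
`ceiling(ratio × n)` training cases: the emulated study splits 86
eligible patients into 61/25, and ceiling is the only rounding
convention that reproduces those sizes (60.2 would round half-up to
60). No stratification is applied, as none is described.

Statistical conventions, chosen to mirror the clinical reporting
style:

* `mann_whitney()` reports U (the smaller pair-count statistic),
  Wilcoxon W = U + n_k(n_k+1)/2 for the group attaining that U, and a
  tie-corrected normal z with a 0.5 continuity correction — the SPSS
  table layout. The W convention is inferred from printed U/W offsets
  and documented rather than guaranteed for all software versions.
* `roc_auc()` uses the Mann-Whitney identity with half credit for
  ties; the AUC variance and 95% CI come from the DeLong structural
  components, computed on the logit scale (stable near 1) and clipped
  to [0, 1]. The operating point maximises Youden's J, with ties
  resolved toward higher sensitivity; the p-value against chance tests
  AUC = 0.5 with the same variance.
* `delong_compare()` is the paired DeLong test; a zero-variance
  difference with equal AUCs returns z = 0, p = 1.
* `fit_logistic()` is the maximum-likelihood GLM fit reporting
  coefficient, SE, Wald = (coef/SE)² and a χ²(1) p-value; separation
  is rejected with a diagnostic. Protein covariates enter as ordinal
  0/1/2 codes (the dummy-coding alternative is not described in the
  emulated analysis).
* `icc_two_rater()` is the two-way random-effects,
  absolute-agreement, single-measure ICC from the mean-squares
  decomposition, with a count of features above 0.75.
* No multiple-testing correction is applied anywhere, matching the
  reporting it emulates; this is a faithful reproduction, not an
  endorsement.

## The synthetic cohort

`sim_config()` defines the study conditions. Defaults: 131 patients
with exclusion counts (5, 10, 4) leaving 112 eligible; LVSI prevalence
0.49; TNC and COX-2 group probabilities conditional on LVSI calibrated
so the marginal group frequencies are near the reported ≈66/26/8%
(TNC) and ≈45/39/16% (COX-2).

PET cases are spheres (default radius 15 mm, ≈14 cm³, comfortably
above the 1-cm³ eligibility floor) of mean SUV 8 over background 1 —
the high FDG avidity typical of cervical SCC, which lets the 42%
threshold separate tumour cleanly. Heterogeneity is a Gaussian random
field (Gaussian-smoothed white noise — simple, seedable and
sufficient to modulate texture), with the LVSI link carried by both
amplitude and spatial scale: field SD 1.0 vs 1.15 and correlation
length 5 vs 3.5 mm for LVSI-negative vs positive. Three
class-independent realism terms keep the planted signal from becoming
degenerate: between-patient variation of the tumour mean SUV
(SD 1.5), uncorrelated voxel noise (SD 0.6, a reconstruction-noise
floor), and log-normal per-case jitter of radius, correlation length
and field SD. Without them, early drafts of the generator made SUVmax
alone a perfect classifier, which contradicts the emulated study
(conventional PET metrics are not significantly associated with LVSI
there); with them, pipeline AUCs land in the study's reported regime
(train ≈ 0.85–0.95, test ≈ 0.75–0.9) and the LASSO typically keeps
10–20 features. The class-heterogeneity ordering is enforced by the
constructor, but equality is allowed so `null_sim_config()` can
produce no-signal cohorts for calibration runs.

All randomness flows from one master seed: every stage (registry,
each PET case, each stain draw, the split, the CV folds) receives a
stream seed from `derive_seed(master, stream)`, so identical
configuration and seed give byte-identical reports.

What the generator does **not** emulate: scanner physics (PSF,
time-of-flight, correlated noise), respiratory motion, realistic
tumour shapes, cell-level stain morphology, or any quantitative
patient-data effect size — the heterogeneity–LVSI link is calibrated
only to make the planted signal recoverable. Passing tests therefore
demonstrate software correctness and statistical calibration, not
clinical performance on real data.

## Pipeline and problem sizes

`run_pipeline()` chains all stages and returns an `eval_report` with
cohort bookkeeping, the LASSO selection, the three models
(radiomics / protein / combined), per-split ROC results, pairwise
DeLong tests, univariate and multivariate tables, and an optional
two-reader ICC sub-study in which a simulated second reader segments
at a different threshold fraction (default 0.38 vs 0.42) on a subset
of training cases (default 12; the emulated study used 40 VOIs).
Should a training set be perfectly separated, the affected model
falls back to a lightly ridge-penalised logistic fit (λ = 0.01 on the
slopes) so evaluation can proceed; the strict ML fit is the default
path and the fallback is marked in the model object.

The test suite exercises Monte-Carlo properties at sizes chosen to
make the statistical checks decisive while keeping a full run
desk-sized: 20 seeded pipeline replicates at 200 eligible patients
for planted-signal recovery and sign recovery, 20 replicates at 120
patients for null calibration (the null criterion fixes no size; 120
is near the emulated cohort's 112), 250 paired cases for the
within-tumour variance ordering, and exhaustive or 10⁵-draw oracles
for the rank statistics.

## Known limitations

* The texture rosters beyond the 16 published feature names (the
  21-feature zone-size roster, the 42-histogram roster, Ng = 64, 2-D
  directions) are package decisions where the emulated analysis is
  silent; they are flagged in the catalogue metadata.
* The face-counting surface area (and everything derived from it) is
  a digital-surface measure, biased high relative to a smooth
  surface.
* The DeLong CI on the logit scale degenerates at AUC = 1 (zero
  variance); the CI then collapses to the point estimate.
* IHC quantification operates on tiles, not whole slides, and does
  not segment nuclei.
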