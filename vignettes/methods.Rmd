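---
title: "Methods: time-resolved serum metabolomics and spatial lipidomics of a TKO HGSC model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved serum metabolomics and spatial lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`metatrack` implements the analysis chain for a longitudinal untargeted
serum metabolomics study of a triple-mutant (TKO) mouse model of
high-grade serous ovarian carcinoma (HGSC), complemented by MALDI mass
spectrometry imaging (MSI) of the reproductive system. The chain runs from
curated feature tables to biomarker panels:

1. QC-based feature curation (blank, QC-presence, QC-RSD filters and
   injection-order drift correction);
2. percent-lifetime alignment and disease-stage binning;
3. Welch / Benjamini-Hochberg feature screening;
4. stage-resolved log2 fold-change trajectories per lipid class;
5. oPLS-DA with venetian-blind cross-validation, genetic-algorithm panel
   selection, and a permutation test on group separation;
6. exhaustive pairwise lipid-ratio biomarker screening with
   cross-validated logistic evaluation;
7. adduct-mass annotation;
8. MSI TIC normalisation, ion images and bisecting k-means segmentation.

The central container is a `feature_table` (features x samples matrix of
non-negative abundances, missing values allowed, with an append-only
provenance log) plus a per-sample metadata table (`sample_records`). MSI
data live in an `msi_dataset` (pixel coordinates with per-pixel centroid
spectra), read and written as imzML 1.1.

Everything is exercisable on synthetic cohorts with planted ground truth;
no external download is required.

# The synthetic cohort generator

`generate_cohort()` emulates the structure of the deposited TKO serum
study (Metabolomics Workbench PR001309 / ST002067): 15 TKO and 15 control
mice bled every two weeks from 8 weeks of age; TKO lifespans drawn uniform
on 24-40 weeks (the model's reported survival range), controls followed to
40 weeks. Roughly 1000 features span 17 lipid classes plus polar
metabolites and unstructured noise features.

Design choices, fixed once as the study conditions:

* **Baselines are log-normal** (log-mean uniform over a wide
  peak-area-like range, e1e4 to e1e6): LC-MS peak areas are strictly
  positive and right-skewed.
* **Temporal effects are multiplicative on the natural scale**,
  `2^(amplitude x template(%lifetime))`, so the planted quantity is
  identical to the reported log2 fold change.
* **Templates** are piecewise-linear anchor curves on the %lifetime axis,
  all anchored at 0 at 20 %lifetime (no premalignant effect): monotone
  up/down drifts (e.g. ceramides up, sphingomyelins down), a
  below-baseline dip-recover-drop arc for lyso-phospholipids, a
  down-up-down wave for amino acids and TCA-cycle metabolites, and a
  late-spike-then-drop template for 20a-hydroxyprogesterone carrying the
  reported magnitudes (+0.99 in the onset/early window, -0.43 in the
  advanced stage). Per-class amplitudes other than 20a-OHP's are not
  reported quantities; the defaults (0.5-1.0 log2 units at template peak)
  are chosen as realistic for serum lipidomics effect sizes and scaled
  globally by `effect_scale`.
* **Measurement noise** is multiplicative log-normal with sdlog 0.4
  (~40% CV), typical of untargeted serum assays; pooled-QC injections are
  drawn with sdlog 0.15, below the 30% RSD filter threshold; blanks sit at
  2% of baseline, far below the 5x blank rule.
* **Missingness is completely at random** (default 5% of study/QC
  entries); informative missingness is out of scope.
* **No mouse-level random baselines by default.** The screening stage
  treats longitudinal samples as independent observations, so the
  generator's null (effect_scale = 0) is calibrated for exactly that
  test; per-mouse aggregation is available via
  `select_significant(per_mouse = TRUE)` for users who want subject-level
  inference. This is the main respect in which passing null-calibration
  tests does not speak to real repeated-measures data.

What the generator does **not** emulate: chromatographic drift in
retention time, isotope patterns, correlated feature blocks within a lipid
class, informative dropout near the detection limit, and batch structure
beyond a single smooth injection-order drift. Recovery results on the
synthetic cohorts therefore demonstrate correctness of the estimators, not
robustness to every artefact of real acquisitions.

The MSI phantom (`generate_msi_phantom()`) partitions a pixel grid into
three contiguous regions — a healthy ovary disk, a necrotic lobe, and an
HGSC field covering the remainder, echoing the tissue anatomy the
segmentation is meant to resolve — with region-specific per-feature
multipliers (default log2 effects ~ N(0, 1.5)), Poisson count noise and a
log-normal per-pixel total-signal factor.

# QC curation

The three removal rules follow the published thresholds: a feature is
background if its mean study abundance is below 5x the mean blank
abundance (the boundary keeps the feature, since removal requires strictly
"less than five times"); unreliable if detected (non-missing and > 0) in
fewer than 50% of pooled-QC injections, or if its QC RSD (n-1 standard
deviation over mean) exceeds 30%. The blank rule compares means — the
choice of mean versus median is not specified in the source protocol, so
the mean is used and documented. Each rule is per-feature and independent,
so the kept set does not depend on rule order (a property the tests
verify). Features with fewer than three usable QC values cannot be
RSD-evaluated and are kept but flagged indeterminate.

Drift correction mirrors a "QC-based regression curve": per feature, a
LOWESS curve (span 0.75) is fitted to QC abundance versus injection order
— simple linear regression when fewer than 5 usable QC points — and
normalised to the median QC level; every sample is divided by the curve
value interpolated at its injection order (held constant beyond the first
and last QC, with extrapolation flagged). The median QC level per feature
is preserved, the correction is idempotent to 1e-9 relative, and on
noiseless linear drift it flattens QC RSD below 1%.

# Percent lifetime and stage bins

Percent lifetime aligns mice with different survival times:
`100 * age / lifespan`, with the control denominator being the age at
last blood collection so both arms populate all bins. The four HGSC stage
bins — PRE (premalignant), ET-I (tumor onset), ET-II (early tumor), AT
(advanced/metastatic) — are realised as half-open real intervals
`[20,37) [37,61) [61,81) [81,100]` over the integer labels 20-36, 37-60,
61-80, 81-100; values below 20, which occur for long-lived controls'
earliest draws, map to PRE. A fine view with fixed-width 5 %lifetime bins
(`fine_bins()`) is provided; whether the original figures used
per-sampling-point or fixed-width bins is not stated, so fixed-width is
the default.

Per-bin group contrast is `log2(mean TKO / mean CTRL)` on raw post-QC
abundances (arithmetic means, matching "content ratios"). The standard
error uses the delta method,
`se = (1/ln 2) * sqrt(cv_T^2/n_T + cv_C^2/n_C)`; the source states only
"standard error" without a formula, and the tests cross-check the delta
form against a bootstrap. Class trajectories average each sample's
abundance over the class's significant features first, then apply the same
per-bin contrast to the class scores.

# Screening

Welch's t-test (Satterthwaite degrees of freedom, two-tailed) runs
per feature with pairwise deletion of missing values — no imputation rule
is given in the source, so none is invented — followed by
Benjamini-Hochberg adjustment; features with q < 0.05 are significant.
The implementation is a vectorised transcription of the textbook formulas
(needed at matrix scale) and is held to `stats::t.test` and a hand-rolled
oracle at 1e-12. BH delegates to `stats::p.adjust`. One spec-level note:
BH step-up is *not* idempotent (reapplying it to q-values can inflate
them), so the tests assert permutation invariance and monotonicity
instead.

# Chemometrics

Matrices are autoscaled (per-feature mean 0, unit sd; zero-variance
columns set to 0 and flagged) before modelling. The oPLS-DA model removes
`n_orth` orthogonal-signal-correction components (structured variation
orthogonal to the class variable) and then fits a single predictive PLS
component; with `n_orth = 0` it reduces exactly to 1-latent-variable
PLS-DA, an identity the tests assert to 1e-10. Class coding is TKO = +1,
CTRL = -1 with decision threshold 0 and ties assigned CTRL
(deterministic). "2-latent-variable" style models use 1 orthogonal
component; the panel model uses 2 (1 predictive + 2 orthogonal, the
"3-latent-variable" shape).

Cross-validation is 10-fold venetian blind: in the fixed sample order
(acquisition order by convention) every 10th sample shares a fold.
Autoscaling is refit inside each training split to avoid leakage (the
source is silent on this; refitting is the conservative choice). At
`n_folds = n` the scheme is exactly leave-one-out, which the tests check
against a direct LOO oracle. Reported metrics are sensitivity (TKO
recall), specificity (CTRL recall), accuracy, and RMSECV of the continuous
class variable.

The permutation test guards against overfitting: "group separation
distance" is not formula-defined in the source, so the conventional
chemometrics statistic is used — the between-class to within-class
sum-of-squares ratio (B/W) of the predictive scores of a model refit per
label permutation — and is recorded in the output metadata. With 1000
iterations the smallest achievable p is 1/1001 < 0.001. The original
oPLS-DA implementation is a commercial toolbox whose internal component
scaling may differ; equivalence is claimed at the level of predictions and
CV metrics, not internal loadings.

# GA panel selection

Binary feature-inclusion chromosomes evolve by size-2 tournament
selection, double-point crossover (single-point for 2-feature problems)
and per-bit mutation (rate 0.005). Fitness is the minimum venetian-blind
RMSECV over 1-3 PLS components on the autoscaled selected submatrix;
all-zero chromosomes score +Inf. The best chromosome always survives
(elitism), making the fitness trace monotone non-increasing — the
invariant the tests use. The run stops when half the population is
identical to the best chromosome or at the generation cap. The source
names the toolbox but no hyperparameters; the defaults (population 64, 100
generations, 15% initial inclusion, 10-fold CV) mirror common GA-PLS
practice, are all carried in `ga_config`, and are logged into the result
for provenance. The published 22-lipid panel emerged unconstrained, so
`max_features` defaults to none.

# Ratio biomarkers

Ratios are computed on the natural scale for every unordered feature pair
(lexicographic orientation), then g-log transformed
(`log2((x + sqrt(x^2 + lambda))/2)`, `lambda` defaulting to the squared
minimum positive value) and autoscaled — matching the stated order of
operations — and ranked by Welch p. The top 20 are each evaluated by
univariate logistic regression under stratified 10-fold CV; pooled
out-of-fold probabilities give the ROC AUC (via pROC) and the operating
point is the Youden-optimal pooled threshold. 95% CIs are percentile
bootstrap over samples (the CI convention of the source tables is unknown
and produces lower bounds equal to the point estimate; that convention is
not reproduced). Stratified folds are used here (class balance per fold);
venetian blinds belong to the chemometrics module. A planted-AUC
construction (`simulate_auc_pair`, binormal equal-variance with
`delta = sqrt(2) qnorm(AUC)`) provides the recovery target of 0.83, the
magnitude of the strongest reported ratio.

# Adduct-mass annotation

Monoisotopic masses are summed from most-abundant-isotope atomic masses;
protonation and deprotonation use the proton mass (1.00727646 Da), and the
electron mass is otherwise neglected (< 0.002 Da, below the 4-decimal
reporting precision). The adduct registry covers [M+H]+, [M-H]-, [M+NH4]+,
[M+CH3COOH-H]- (acetate) and [M+H2CO2-H]- (formate). Matching is plain
ppm-tolerance exact-mass search (default 5 ppm), sorted by |ppm|;
matches get annotation confidence level 3 (exact mass only), unmatched
observations level 4 — levels 1-2 require MS/MS evidence supplied by the
user and are never inferred. The two shipped reference tables (14 polar
metabolites; the 22-lipid panel) form a desk-scale regression suite: every
printed experimental m/z must sit within 5 ppm of the theoretical
formula+adduct mass. Some printed per-row mass errors are not exactly
reproducible from 4-decimal m/z values due to rounding, so the 5 ppm
envelope, not the printed errors, is asserted.

# MSI segmentation

Per-pixel spectra are TIC-normalised (each pixel sums to 1); ion images
sum intensities within an absolute +-0.001 Da window (an absolute window,
not ppm, per the imaging convention used). Segmentation is bisecting
k-means: the cluster with the largest within-cluster SSE is repeatedly
split by 2-means, keeping the best of 10 seeded restarts, until k clusters
exist; the split tree with SSE before/after is recorded. The default
metric is cosine dissimilarity, implemented exactly as Euclidean 2-means
on L2-normalised rows (the two objectives are monotonically equivalent on
the unit sphere); Euclidean on TIC-normalised rows is available. The
cluster-to-split rule (largest SSE, not largest cardinality) and the
metric are free choices documented here and configurable. No hot-spot
clipping or denoising is applied by default since none is described for
the original workflow; clustering operates on a user-supplied reference
m/z list (e.g. annotated features), which may differ from the original
software's internal preprocessing.

The imzML writer emits processed-mode 1.1 files (64-bit m/z, 32-bit
intensity, little-endian, uncompressed) with the imaging-MS
controlled-vocabulary parameters; the reader accepts processed and
continuous mode. Conformance was checked against an independent Python
imzML parser during development.

# Numerical and degenerate-input conventions

* Zero-variance features: autoscale flags and zeroes them; Welch returns
  p = 1 when both groups are constant and equal, an error when constant
  and unequal.
* Zero denominators: ratio entries become missing; region fold changes
  flag the feature `NA`; a zero control mean in a trajectory bin is an
  error rather than an infinity.
* Ties at the oPLS-DA decision threshold go to CTRL.
* All stochastic steps (generator, GA, 2-means restarts, permutations,
  bootstrap, fold assignment) consume an explicit seed and restore the
  caller's RNG state; identical configs give byte-identical outputs.
* `run_pipeline` expands one global seed into fixed per-stage offsets so
  stages are reproducible in isolation.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script problem sizes are chosen to exercise
the estimators at the study's own scale while keeping runs desk-sized:
null calibration uses the full 15+15-mouse, ~1000-feature design over 10-20
seeds; panel recovery plants 22 discriminant features among 300 at one
autoscaled SD with n = 60 (the onset-window sample count's order of
magnitude); ratio recovery screens 1035 ratios from 46 features over 20
seeds; the MSI phantom is 30x30 pixels with 50 features. Trajectory
recovery runs at `effect_scale = 0.5` (half the default amplitudes) to
show sign patterns survive attenuated effects; the 20a-OHP check runs at
the template's own planted magnitudes.

# Known limitations

* No repeated-measures modelling: samples are treated as independent in
  screening, mirroring the source analysis; the per-mouse option exists
  but is not the default.
* MS/MS-based annotation (confidence 1-2), isotope-pattern scoring and
  decoy-FDR annotation of MSI features are out of scope; annotation is
  exact-mass only.
* The GA explores a stochastic subset of panel space; different seeds can
  return different panels of similar RMSECV, as wrapper selection always
  does.
* Trajectories are unsmoothed bin contrasts; no splines or mixed models.
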