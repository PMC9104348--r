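# metatrack

Time-resolved serum metabolomics and spatial lipidomics analysis for a
triple-mutant (TKO) mouse model of high-grade serous ovarian carcinoma
(HGSC).

HGSC is the deadliest ovarian cancer subtype, usually diagnosed after
metastasis. Longitudinal serum profiling of a mouse model that develops
HGSC with full penetrance lets metabolic changes be tracked from
premalignant stages to death, and tissue mass spectrometry imaging (MSI)
shows where in the reproductive system those lipid changes originate.
`metatrack` implements that analysis chain as a tested R package for
analysts working with longitudinal untargeted LC-MS feature tables and
MALDI imaging data, with a synthetic-cohort generator (planted ground
truth) so every step can be validated without access to the original
instruments.

## What it computes

* **QC feature curation** — pooled-QC based cleanup: features are removed
  when mean study abundance < 5 x mean blank abundance, when detected in
  < 50% of QC injections, or when QC RSD > 30%; a LOWESS curve of QC
  abundance vs injection order corrects instrument drift.
* **Percent-lifetime alignment** — each sample is placed at
  `100 * age / lifespan` (for controls, age at last collection), binned
  into disease stages: PRE [20,37), ET-I [37,61), ET-II [61,81),
  AT [81,100].
* **Trajectories** — per lipid class, the per-bin contrast
  `log2(mean TKO / mean CTRL)` of class scores (mean abundance over the
  class's significant features), with delta-method standard errors
  `se = (1/ln 2) * sqrt(cv_T^2/n_T + cv_C^2/n_C)`.
* **Screening** — two-tailed Welch t-tests per feature with
  Benjamini-Hochberg control (q < 0.05).
* **Panels** — genetic-algorithm feature selection (fitness = minimum
  10-fold venetian-blind PLS RMSECV over 1-3 latent variables), an
  oPLS-DA model (orthogonal signal correction + 1 predictive component)
  on the selected panel, 10-fold venetian-blind CV
  (sensitivity/specificity/accuracy), and a 1000-iteration permutation
  test on the between/within sum-of-squares ratio (B/W) of the
  predictive scores.
* **Ratio biomarkers** — all C(m,2) pairwise abundance ratios, g-log
  (`log2((x + sqrt(x^2+lambda))/2)`) + autoscaling, Welch ranking, and
  10-fold cross-validated logistic evaluation of the top 20 (ROC AUC,
  Youden-point sensitivity/specificity, bootstrap 95% CIs).
* **Annotation** — monoisotopic masses from elemental formulas, adduct
  m/z for [M+H]+, [M-H]-, [M+NH4]+, acetate and formate adducts, and
  ppm-tolerance matching with mechanical confidence levels.
* **MSI** — imzML 1.1 read/write, TIC normalisation, +-0.001 Da ion
  images, bisecting k-means segmentation (cosine metric) with split-tree
  reporting, and region-vs-region log2 fold changes.

The vignette (`vignettes/methods.Rmd`) documents the model assumptions,
parameter choices and limitations.

## Worked example

The `analysis/` directory holds the end-to-end workflow as numbered
drivers (simulate, QC, screen + trajectories, panel, ratios, MSI), each
writing its tables under `results/`. Running them in order prints, for
the default synthetic cohort (15 TKO + 15 control mice, ~1000 features):

```
$ Rscript analysis/03_screen_trajectories.R
significant features (q < 0.05): 710 of 1001 overall, 354 in the 37-60% window
stage-bin trajectories (log2 TKO/CTRL):
  SM   PRE -0.07  ET1 -0.25  ET2 -0.51  AT -0.68
  Cer  PRE +0.08  ET1 +0.30  ET2 +0.47  AT +0.67
  LPC  PRE -0.20  ET1 -0.48  ET2 -0.17  AT -0.49
  OHP  PRE +0.02  ET1 +0.90  ET2 +1.06  AT -0.26
```

Sphingomyelins fall and ceramides rise monotonically with disease
progression; lysophosphatidylcholines dip, partially recover, then fall;
20a-hydroxyprogesterone spikes at tumor onset and reverses in the
advanced stage — each trajectory recovering the temporal template planted
by the generator.

```
$ Rscript analysis/04_panel_model.R
GA selected 145 features in 100 generations (RMSECV 0.201, 1 LV)
panel oPLS-DA 10-fold CV: sensitivity 100.0%, specificity 100.0%, accuracy 100.0%
permutation test (1000 iterations, B/W statistic): p = 0.000999

$ Rscript analysis/05_ratio_biomarkers.R
screening 46 features -> 1035 candidate ratios
top 5 lipid-ratio biomarkers:
  F0025/F0327    p = 8.63e-29  AUC 0.798 (0.756-0.842)  sens 0.68  spec 0.81
  F0025/F0284    p = 4.78e-28  AUC 0.796 (0.749-0.833)  sens 0.74  spec 0.73
  ...
```

The top ratios pair a rising ceramide (numerator) with falling
lyso-/ether-phospholipids (denominator) — the ratio construction amplifies
two opposite temporal trends into a single marker. The MSI driver
segments the 3-region phantom (HGSC field / necrotic lobe / healthy
ovary) with adjusted Rand index 1.000 against the planted labels.

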