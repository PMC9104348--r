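Package: metatrack
Title: Time-Resolved Serum Metabolomics and Spatial Lipidomics of an Ovarian Cancer Mouse Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal (time-resolved) untargeted serum
    metabolomics and MALDI mass spectrometry imaging (MSI) lipidomics of a
    triple-mutant (TKO) mouse model of high-grade serous ovarian carcinoma.
    Implements pooled-QC based feature curation (blank, QC-presence and QC-RSD
    filters, injection-order drift correction), percent-lifetime alignment with
    disease-stage binning, stage-resolved log2 fold-change trajectories per
    lipid class, Welch/Benjamini-Hochberg feature screening, orthogonal PLS-DA
    with venetian-blind cross-validation and a permutation test on group
    separation, genetic-algorithm panel selection minimising PLS RMSECV,
    exhaustive pairwise lipid-ratio biomarker screening with cross-validated
    logistic regression, monoisotopic adduct-mass annotation, and bisecting
    k-means spatial segmentation of imzML imaging data. A synthetic-cohort and
    MSI-phantom generator with planted ground truth supports recovery testing
    of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
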