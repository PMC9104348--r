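#!/usr/bin/env Rscript
# Stage 5: pairwise lipid-ratio biomarker screening. All C(m,2) ratios over
# the screened features, g-log + autoscale, Welch ranking, and 10-fold
# cross-validated logistic evaluation (AUC / sensitivity / specificity with
# bootstrap 95% CIs) of the top 20.

library(metatrack)

outdir <- "results/ratios"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

inp <- read_feature_table("results/qc/features_curated.tsv",
                          "results/qc/samples.tsv")
welch <- read.delim("results/screen/welch_onset_window.tsv")

# cap the all-pairs stage at the 46 strongest screened features
o <- order(welch$q)
sig <- head(welch$feature_id[o][!is.na(welch$q[o]) & welch$q[o] < 0.05], 46)
cat(sprintf("screening %d features -> %d candidate ratios\n",
            length(sig), choose(length(sig), 2)))

rep <- ratio_biomarker_screen(inp$table, inp$records, feature_ids = sig,
                              top_k = 20, n_folds = 10, n_boot = 500,
                              seed = 77)
write.table(rep, file.path(outdir, "ratio_biomarkers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("top 5 lipid-ratio biomarkers:\n")
top <- head(rep, 5)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-14s p = %8.2e  AUC %.3f (%.3f-%.3f)  sens %.2f  spec %.2f\n",
              top$ratio[i], top$p[i], top$auc[i], top$auc_lo[i],
              top$auc_hi[i], top$sensitivity[i], top$specificity[i]))
}
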