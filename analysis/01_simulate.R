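#!/usr/bin/env Rscript
# Stage 1: generate the synthetic longitudinal serum cohort under the study
# conditions (15 TKO + 15 control mice, biweekly sampling from 8 weeks,
# ~1000 features over 17 lipid classes + polar metabolites + noise) and
# write it to disk as the delimited-text exchange format the rest of the
# workflow consumes.

library(metatrack)

outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260929, drift_fold = 1.5)
sim <- generate_cohort(cfg)

write_feature_table(sim$table, sim$records,
                    file.path(outdir, "features.tsv"),
                    file.path(outdir, "samples.tsv"))
write.table(sim$truth$features, file.path(outdir, "truth_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d features x %d samples (%d study, %d QC, %d blank)\n",
            nrow(sim$table$abund), ncol(sim$table$abund),
            sum(sim$records$group %in% c("TKO", "CTRL")),
            sum(sim$records$group == "QC"),
            sum(sim$records$group == "BLANK")))
cat(sprintf("TKO lifespans: %.1f-%.1f weeks\n",
            min(sim$truth$lifespans[grep("^TKO", names(sim$truth$lifespans))]),
            max(sim$truth$lifespans[grep("^TKO", names(sim$truth$lifespans))])))
cat("wrote", file.path(outdir, "features.tsv"), "\n")
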