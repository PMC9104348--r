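#!/usr/bin/env Rscript
# Stage 2: QC feature curation. Corrects pooled-QC injection-order drift,
# then applies the three removal rules (5x-over-blank, 50% QC presence,
# 30% QC RSD) and writes the curated table plus per-rule reports.

library(metatrack)

indir <- "results/cohort"
outdir <- "results/qc"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

inp <- read_feature_table(file.path(indir, "features.tsv"),
                          file.path(indir, "samples.tsv"))

out <- qc_pipeline(inp$table, inp$records,
                   blank_factor = 5, min_fraction = 0.5, max_rsd = 0.30,
                   drift = TRUE)

write_feature_table(out$table, inp$records,
                    file.path(outdir, "features_curated.tsv"),
                    file.path(outdir, "samples.tsv"))
for (nm in names(out$reports)) {
  write.table(out$reports[[nm]], file.path(outdir, paste0("qc_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf("kept %d of %d features (removed: blank %d, presence %d, rsd %d)\n",
            nrow(out$table$abund), nrow(inp$table$abund),
            out$n_removed["blank"], out$n_removed["presence"],
            out$n_removed["rsd"]))
qcs <- inp$records$sample_id[inp$records$group == "QC"]
rsd <- function(m) median(apply(m[, qcs], 1, function(v)
  sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)), na.rm = TRUE)
cat(sprintf("median QC RSD: %.3f before drift correction, %.3f after\n",
            rsd(inp$table$abund), rsd(out$table$abund)))
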