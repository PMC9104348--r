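#!/usr/bin/env Rscript
# Stage 4: discriminant panel discovery in the tumor-onset window. GA
# feature selection (fitness = venetian-blind PLS RMSECV) over the
# screened features, a 3-latent-variable-style oPLS-DA on the selected
# panel (1 predictive + 2 orthogonal components), 10-fold venetian-blind
# CV, and a 1000-iteration permutation test on group-separation distance.

library(metatrack)

outdir <- "results/panel"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

inp <- read_feature_table("results/qc/features_curated.tsv",
                          "results/qc/samples.tsv")
sig <- readLines("results/screen/significant_onset.txt")

win_ids <- inp$records$sample_id[
  !is.na(inp$records$pct_lifetime) &
    inp$records$pct_lifetime >= 37 & inp$records$pct_lifetime < 61]
labels <- inp$records$group[match(win_ids, inp$records$sample_id)]
X <- t(inp$table$abund[sig, win_ids, drop = FALSE])
X[is.na(X)] <- 0

res <- ga_feature_select(X, labels, ga_config(seed = 11))
cat(sprintf("GA selected %d features in %d generations (RMSECV %.3f, %d LV)\n",
            length(res$selected_idx), res$generations, res$best_rmsecv,
            res$best_lv))
writeLines(res$selected, file.path(outdir, "panel_features.txt"))
write.table(data.frame(generation = seq_along(res$trace),
                       best_rmsecv = res$trace),
            file.path(outdir, "ga_trace.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

panel <- X[, res$selected_idx, drop = FALSE]
cv <- venetian_blind_cv(panel, labels, n_orth = 2, n_folds = 10)
cat(sprintf("panel oPLS-DA 10-fold CV: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
            100 * cv$sensitivity, 100 * cv$specificity, 100 * cv$accuracy))

pt <- permutation_test(panel, labels, n_orth = 2, n_perm = 1000, seed = 12)
cat(sprintf("permutation test (1000 iterations, B/W statistic): p = %.4g\n",
            pt$p))

write.table(data.frame(metric = c("sensitivity", "specificity", "accuracy",
                                  "rmsecv", "permutation_p"),
                       value = c(cv$sensitivity, cv$specificity, cv$accuracy,
                                 cv$rmsecv, pt$p)),
            file.path(outdir, "panel_cv.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
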