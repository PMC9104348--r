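#' Run the end-to-end analysis on a synthetic cohort
#'
#' Orchestrates the full chain — simulate, QC curation, univariate
#' screening, stage trajectories, GA panel + oPLS-DA cross-validation +
#' permutation test, ratio biomarkers, MSI phantom segmentation — writing
#' per-stage tab-separated outputs and a plain-text summary under `outdir`.
#' A single global seed is expanded into fixed per-stage seeds so each
#' stage is reproducible in isolation; two runs with the same config are
#' byte-identical.
#'
#' @param config a [sim_config()] for the serum cohort.
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @param alpha FDR level of the screening stage.
#' @param screen_window %lifetime window for the panel screening stage
#'   (default the tumor-onset window `c(37, 61)`).
#' @param ga GA settings as a [ga_config()]; `NULL` skips the panel stage.
#' @param n_orth orthogonal components for the panel oPLS-DA.
#' @param n_perm permutation-test iterations (0 skips).
#' @param top_k_ratios ratios to evaluate (0 skips the ratio stage).
#' @param ratio_screen_max cap on the number of screened features entering
#'   the all-pairs ratio stage (smallest q first), keeping the pair count
#'   tractable.
#' @param msi run the MSI phantom + segmentation stage.
#' @return list of class `pipeline_report` with per-stage results and
#'   counts.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, alpha = 0.05,
                         screen_window = c(37, 61), ga = ga_config(),
                         n_orth = 2, n_perm = 1000, top_k_ratios = 20,
                         ratio_screen_max = 46, msi = TRUE) {
  t0 <- Sys.time()
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, df) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
  }
  report <- list(config = config)

  sim <- generate_cohort(config)
  report$n_features_raw <- nrow(sim$table$abund)
  report$n_samples <- sum(is_study(sim$records))

  qc <- qc_pipeline(sim$table, sim$records, drift = config$drift_fold != 1)
  report$qc_removed <- qc$n_removed
  report$n_features_qc <- nrow(qc$table$abund)

  sel_all <- select_significant(qc$table, sim$records, alpha = alpha)
  sel_win <- select_significant(qc$table, sim$records, alpha = alpha,
                                window = screen_window)
  report$n_significant_all <- length(sel_all$significant)
  report$n_significant_window <- length(sel_win$significant)
  emit("screen_all", sel_all$results)
  emit("screen_window", sel_win$results)

  traj <- do.call(rbind, lapply(
    setdiff(unique(sim$truth$features$lipid_class), "noise"),
    function(cl) {
      suppressWarnings(class_trajectory(
        qc$table, sim$truth$features, sim$records, cl, sel_all$significant
      ))
    }
  ))
  report$trajectories <- traj
  emit("trajectories", traj)

  study_ids <- group_samples(sim$records, c("TKO", "CTRL"))
  labels <- sim$records$group[match(study_ids, sim$records$sample_id)]

  if (!is.null(ga) && length(sel_win$significant) >= 2) {
    win_ids <- samples_in_bin(sim$records, screen_window)
    win_labels <- sim$records$group[match(win_ids, sim$records$sample_id)]
    Xw <- t(qc$table$abund[sel_win$significant, win_ids, drop = FALSE])
    Xw[is.na(Xw)] <- 0
    panel <- ga_feature_select(Xw, win_labels, config = ga)
    cv <- venetian_blind_cv(Xw[, panel$selected_idx, drop = FALSE],
                            win_labels, n_orth = n_orth)
    report$panel <- panel$selected
    report$panel_rmsecv <- panel$best_rmsecv
    report$panel_cv <- cv[c("sensitivity", "specificity", "accuracy", "rmsecv")]
    if (n_perm > 0) {
      pt <- permutation_test(Xw[, panel$selected_idx, drop = FALSE],
                             win_labels, n_orth = n_orth, n_perm = n_perm,
                             seed = config$seed + 1000)
      report$permutation_p <- pt$p
      report$permutation_observed <- pt$observed
    }
    emit("panel", data.frame(feature_id = panel$selected))
  } else if (!is.null(ga)) {
    report$panel <- character(0)
    report$panel_note <- "panel stage skipped: fewer than 2 screened features"
  }

  if (top_k_ratios > 0 && length(sel_all$significant) >= 2) {
    ratio_ids <- utils::head(
      sel_all$results$feature_id[order(sel_all$results$q)][
        sel_all$results$feature_id[order(sel_all$results$q)] %in%
          sel_all$significant],
      ratio_screen_max)
    ratios <- ratio_biomarker_screen(
      qc$table, sim$records, feature_ids = ratio_ids, top_k = top_k_ratios,
      n_boot = 0, seed = config$seed + 2000
    )
    report$ratios <- ratios
    emit("ratio_biomarkers", ratios)
  } else if (top_k_ratios > 0) {
    report$ratio_note <- "ratio stage skipped: fewer than 2 screened features"
  }

  if (msi) {
    ph <- generate_msi_phantom(seed = config$seed + 3000)
    pm <- build_pixel_matrix(ph$dataset, ph$truth$mz, tol_da = 0.001)
    seg <- bisecting_kmeans_segment(pm, k = 3, seed = config$seed + 3001)
    report$msi_k <- 3
    report$msi_cluster_sizes <- as.integer(table(seg$cluster))
    report$msi_truth_regions <- ph$truth$region
    report$msi_cluster <- seg$cluster
    fc <- region_log2fc(pm, ph$truth$region, "HGSC", "healthy")
    report$msi_region_log2fc <- fc
    if (!is.null(outdir)) {
      write_region_raster(ph$dataset$coords, seg$cluster,
                          file.path(outdir, "segmentation.txt"))
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) {
    writeLines(utils::capture.output(print(report)),
               file.path(outdir, "report.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== metatrack pipeline report ==\n")
  cat(sprintf("samples: %d study; features: %d raw -> %d post-QC\n",
              x$n_samples, x$n_features_raw, x$n_features_qc))
  cat(sprintf("QC removals: blank %d, presence %d, rsd %d\n",
              x$qc_removed["blank"], x$qc_removed["presence"],
              x$qc_removed["rsd"]))
  cat(sprintf("significant features: %d (all samples), %d (screen window)\n",
              x$n_significant_all, x$n_significant_window))
  if (!is.null(x$panel) && length(x$panel)) {
    cat(sprintf("panel: %d features, RMSECV %.3f; CV sens %.3f spec %.3f acc %.3f\n",
                length(x$panel), x$panel_rmsecv, x$panel_cv$sensitivity,
                x$panel_cv$specificity, x$panel_cv$accuracy))
  }
  if (!is.null(x$permutation_p)) {
    cat(sprintf("permutation test: p = %.6f (observed B/W %.3f)\n",
                x$permutation_p, x$permutation_observed))
  }
  if (!is.null(x$ratios)) {
    cat(sprintf("top ratio: %s (AUC %.3f)\n", x$ratios$ratio[1],
                x$ratios$auc[1]))
  }
  if (!is.null(x$msi_cluster)) {
    cat(sprintf("msi segmentation: k=%d, cluster sizes %s\n", x$msi_k,
                paste(x$msi_cluster_sizes, collapse = "/")))
  }
  cat(sprintf("elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
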