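test_that("template evaluation is piecewise linear with clamped ends", {
  flat <- planted_template("flat")
  expect_equal(template_value(flat, c(0, 33, 100)), c(0, 0, 0))
  up <- planted_template("monotone_up", anchors = c("20" = 0, "100" = 1))
  expect_equal(template_value(up, 60), 0.5)
  expect_equal(template_value(up, 10), 0)   # clamped below range
  expect_equal(template_value(up, 100), 1)
  wav <- planted_template("wave_down_up_down",
                          anchors = c("20" = 0, "45" = -0.4, "70" = 0.3,
                                      "100" = -0.5))
  expect_equal(template_value(wav, 45), -0.4)
  expect_error(planted_template("flat", anchors = numeric(0)), "non-empty")
  # all default templates anchor at zero at 20 %lifetime
  for (sh in c("flat", "monotone_up", "monotone_down", "inverted_U",
               "wave_down_up_down", "late_spike_then_drop")) {
    expect_equal(template_value(planted_template(sh), 20), 0, info = sh)
  }
})

test_that("identical configs give byte-identical cohorts", {
  a <- generate_cohort(small_config(seed = 42))
  b <- generate_cohort(small_config(seed = 42))
  expect_identical(a$table$abund, b$table$abund)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$features, b$truth$features)
  c <- generate_cohort(small_config(seed = 43))
  expect_false(identical(a$table$abund, c$table$abund))
})

test_that("a cohort without TKO mice has only ctrl, QC and blank samples", {
  sim <- generate_cohort(sim_config(
    n_tko = 0, n_ctrl = 2,
    n_features_per_class = c(Cer = 2), n_noise_features = 2, seed = 1
  ))
  expect_setequal(unique(sim$records$group), c("CTRL", "QC", "BLANK"))
  expect_error(generate_cohort(sim_config(n_tko = 0, n_ctrl = 0)), "no mice")
})

test_that("cohort structure matches the configured design", {
  cfg <- small_config(seed = 2)
  sim <- generate_cohort(cfg)
  recs <- sim$records
  expect_equal(length(unique(recs$mouse_id[recs$group == "TKO"])), cfg$n_tko)
  expect_equal(length(unique(recs$mouse_id[recs$group == "CTRL"])), cfg$n_ctrl)
  # sampling every 2 weeks from 8 weeks of age
  one <- recs[recs$mouse_id %in% recs$mouse_id[which(recs$group == "TKO")[1]], ]
  expect_equal(min(one$age_weeks), 8)
  expect_true(all(diff(sort(one$age_weeks)) == 2))
  # TKO lifespans within the configured range; ctrl followed to 40 weeks
  tko_life <- unique(recs$lifespan_weeks[recs$group == "TKO"])
  expect_true(all(tko_life >= 24 & tko_life <= 40))
  expect_true(all(recs$lifespan_weeks[recs$group == "CTRL"] == 40))
  # injection order unique and complete
  expect_equal(sort(recs$injection_order), seq_len(nrow(recs)))
  # truth covers every feature, noise features flat with zero amplitude
  expect_equal(nrow(sim$truth$features), nrow(sim$table$abund))
  noise <- sim$truth$features$lipid_class == "noise"
  expect_true(all(sim$truth$features$amplitude[noise] == 0))
})

test_that("realised QC dispersion tracks the configured target", {
  cfg <- small_config(seed = 3, qc_rsd_target = 0.15, dropout_fraction = 0)
  sim <- generate_cohort(cfg)
  qcs <- sim$records$sample_id[sim$records$group == "QC"]
  rsd <- apply(sim$table$abund[, qcs], 1, function(v) sd(v) / mean(v))
  expect_lt(abs(mean(rsd) - 0.15) / 0.15, 0.30)
})

test_that("blank samples sit at the configured fraction of baseline", {
  cfg <- small_config(seed = 4, blank_level = 0.02, dropout_fraction = 0)
  sim <- generate_cohort(cfg)
  blanks <- sim$records$sample_id[sim$records$group == "BLANK"]
  study <- sim$records$sample_id[is_study <- sim$records$group %in% c("TKO", "CTRL")]
  ratio <- rowMeans(sim$table$abund[, blanks]) /
    rowMeans(sim$table$abund[, study])
  expect_lt(median(ratio), 0.05)
})

test_that("dropout fraction controls missingness in study/QC entries", {
  sim0 <- generate_cohort(small_config(seed = 5, dropout_fraction = 0))
  expect_false(anyNA(sim0$table$abund))
  sim <- generate_cohort(small_config(seed = 5, dropout_fraction = 0.1))
  blanks <- grepl("^BLANK", colnames(sim$table$abund))
  frac <- mean(is.na(sim$table$abund[, !blanks]))
  expect_equal(frac, 0.1, tolerance = 0.01)
  expect_false(anyNA(sim$table$abund[, blanks]))
})

test_that("null cohorts produce calibrated Welch p-values", {
  # effect_scale = 0: TKO and ctrl identically distributed
  ps <- unlist(lapply(1:5, function(s) {
    sim <- generate_cohort(sim_config(
      n_tko = 8, n_ctrl = 8, effect_scale = 0,
      n_features_per_class = c(Cer = 50, SM = 50), n_noise_features = 100,
      seed = s
    ))
    study <- sim$records$sample_id[sim$records$group %in% c("TKO", "CTRL")]
    grp <- sim$records$group[match(study, sim$records$sample_id)]
    welch_t_matrix(sim$table$abund[, study], which(grp == "TKO"),
                   which(grp == "CTRL"))$p
  }))
  frac <- mean(ps < 0.05, na.rm = TRUE)
  n <- sum(!is.na(ps))
  expect_lt(abs(frac - 0.05), 2.6 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("planted stage-bin fold changes converge to the template value", {
  # large per-bin n: empirical log2FC within 3 se of the planted anchor
  cfg <- sim_config(n_tko = 40, n_ctrl = 40,
                    n_features_per_class = c(Cer = 10), n_noise_features = 0,
                    dropout_fraction = 0, seed = 6)
  sim <- generate_cohort(cfg)
  tmpl <- sim$truth$templates[["monotone_up"]]
  amp <- sim$truth$features$amplitude[1]
  for (bin in c("ET2", "AT")) {
    planted <- amp * metatrack:::template_bin_mean(tmpl, bin)
    pt <- bin_log2_fold_change(sim$table, sim$records,
                               sim$truth$features$feature_id[1], bin)
    expect_lt(abs(pt$log2fc - planted), 3 * pt$se)
  }
})

test_that("planted AUC construction hits its binormal target", {
  p <- simulate_auc_pair(4000, auc = 0.83, seed = 8)
  lab <- p$labels == "TKO"
  # empirical AUC by rank statistic (Mann-Whitney)
  r <- rank(p$value)
  auc_hat <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_equal(auc_hat, 0.83, tolerance = 0.02)
})

test_that("MSI phantom partitions the grid and plants region effects", {
  ph <- generate_msi_phantom(20, 20, 10, seed = 2)
  expect_equal(length(ph$truth$region), 400)
  expect_setequal(unique(ph$truth$region), c("HGSC", "necrotic", "healthy"))
  # every pixel labelled exactly once; spectra cover all pixels
  expect_equal(nrow(ph$dataset$coords), 400)
  # planted multiplier 4x in one region recovers log2fc ~ 2 on truth labels
  eff <- list(healthy = 1, HGSC = 4, necrotic = 1)
  ph2 <- generate_msi_phantom(20, 20, 5, region_effects = eff, seed = 3,
                              mean_counts = 2000)
  pm <- build_pixel_matrix(ph2$dataset, ph2$truth$mz)
  fc <- region_log2fc(pm, ph2$truth$region, "HGSC", "healthy")
  expect_equal(unname(fc), rep(2, 5), tolerance = 0.1)
  expect_error(generate_msi_phantom(1, 5, 3), "2 x 2")
})

test_that("phantoms are deterministic given the seed", {
  a <- generate_msi_phantom(10, 10, 5, seed = 9)
  b <- generate_msi_phantom(10, 10, 5, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$dataset$intensity, b$dataset$intensity)
})
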