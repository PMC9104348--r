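# fixed small run: 4 study, 4 QC, 2 blank samples
qc_fixture <- function(m_study, m_qc, m_blank) {
  n <- ncol(m_study) + ncol(m_qc) + ncol(m_blank)
  labels <- c(rep(c("TKO", "CTRL"), length.out = ncol(m_study)),
              rep("QC", ncol(m_qc)), rep("BLANK", ncol(m_blank)))
  recs <- flat_records(labels)
  m <- cbind(m_study, m_qc, m_blank)
  colnames(m) <- recs$sample_id
  rownames(m) <- sprintf("F%02d", seq_len(nrow(m)))
  list(table = feature_table(m), records = recs)
}

test_that("blank filter applies the 5x-over-blank rule with >= boundary", {
  m_study <- matrix(c(99, 100, 50), 3, 4)   # study mean per feature
  m_qc <- matrix(c(99, 100, 50), 3, 4)
  m_blank <- matrix(c(20, 20, 0), 3, 2)     # blank means 20, 20, 0
  fx <- qc_fixture(m_study, m_qc, m_blank)
  out <- blank_filter(fx$table, fx$records, factor = 5)
  # 99 < 5*20 removed; 100 >= 100 kept (boundary); zero blank always kept
  expect_equal(out$report$keep, c(FALSE, TRUE, TRUE))
  expect_equal(rownames(out$table$abund), c("F02", "F03"))
  expect_equal(out$n_removed, 1)
  # no blanks present -> explicit error
  fx2 <- qc_fixture(m_study, m_qc, matrix(numeric(0), 3, 0))
  expect_error(blank_filter(fx2$table, fx2$records), "no blank")
})

test_that("QC presence filter keeps features seen in >= 50% of QCs", {
  m_qc <- rbind(c(1, 1, 1, 1, 1, NA, NA, NA, NA, NA),  # 5/10 -> kept
                c(1, 1, 1, 1, NA, NA, NA, NA, NA, NA), # 4/10 -> removed
                rep(NA, 10),                           # 0/10 -> removed
                c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))       # zeros not "present"
  m_study <- matrix(5, 4, 4)
  fx <- qc_fixture(m_study, m_qc, matrix(0.1, 4, 2))
  out <- qc_presence_filter(fx$table, fx$records)
  expect_equal(out$report$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$report$qc_presence_fraction, c(0.5, 0.4, 0, 0.4))
  fx1 <- qc_fixture(m_study, m_qc[, 1, drop = FALSE], matrix(0.1, 4, 2))
  expect_error(qc_presence_filter(fx1$table, fx1$records), ">= 2 QC")
})

test_that("QC RSD filter uses the n-1 standard deviation over QCs", {
  m_qc <- rbind(c(100, 110, 90),  # sd 10, mean 100 -> RSD 0.10, kept
                c(50, 50, 50),    # RSD 0 -> kept
                c(10, 100, 190),  # sd 90, mean 100 -> RSD 0.9, removed
                c(100, NA, NA))   # <3 usable -> indeterminate, kept
  m_study <- matrix(5, 4, 4)
  fx <- qc_fixture(m_study, m_qc, matrix(0.1, 4, 2))
  out <- qc_rsd_filter(fx$table, fx$records, max_rsd = 0.30)
  expect_equal(out$report$qc_rsd[1], 0.10, tolerance = 1e-12)
  expect_equal(out$report$qc_rsd[3], 0.90, tolerance = 1e-12)
  expect_equal(out$report$keep, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(out$report$indeterminate[4])
})

test_that("the three removal rules commute", {
  set.seed(31)
  sim <- generate_cohort(small_config(seed = 31, dropout_fraction = 0.2,
                                      blank_level = 0.5))
  orders <- list(
    c("blank", "presence", "rsd"),
    c("rsd", "blank", "presence"),
    c("presence", "rsd", "blank")
  )
  apply_rule <- function(tab, rule) {
    switch(rule,
           blank = blank_filter(tab, sim$records)$table,
           presence = qc_presence_filter(tab, sim$records)$table,
           rsd = qc_rsd_filter(tab, sim$records)$table)
  }
  kept <- lapply(orders, function(o) {
    tab <- sim$table
    for (r in o) tab <- apply_rule(tab, r)
    rownames(tab$abund)
  })
  expect_equal(kept[[1]], kept[[2]])
  expect_equal(kept[[1]], kept[[3]])
})

test_that("drift correction flattens a linear 2x drift and is idempotent", {
  # noiseless constructed run: QCs every 3rd injection, linear 2x drift
  n <- 31
  labels <- rep("TKO", n)
  labels[seq(1, n, by = 3)] <- "QC"
  labels[seq(2, n, by = 6)] <- "CTRL"
  recs <- flat_records(labels)
  drift <- seq(1, 2, length.out = n)
  base <- c(1000, 500)
  m <- outer(base, drift)
  dimnames(m) <- list(c("A", "B"), recs$sample_id)
  tab <- feature_table(m)
  out <- qc_drift_correct(tab, recs)
  qcs <- recs$sample_id[recs$group == "QC"]
  rsd_after <- apply(out$table$abund[, qcs], 1, function(v) sd(v) / mean(v))
  expect_true(all(rsd_after < 0.01))
  # median QC level preserved per feature
  expect_equal(apply(out$table$abund[, qcs], 1, median),
               apply(m[, qcs], 1, median), tolerance = 0.02,
               ignore_attr = TRUE)
  # idempotence: correcting corrected data changes nothing (1e-9 relative)
  out2 <- qc_drift_correct(out$table, recs)
  expect_equal(out2$table$abund, out$table$abund, tolerance = 1e-9)
  # constant QCs leave data untouched
  m_flat <- matrix(rep(c(1000, 500), n), 2, n,
                   dimnames = dimnames(m))
  flat <- qc_drift_correct(feature_table(m_flat), recs)
  expect_equal(flat$table$abund, m_flat, tolerance = 1e-12)
})

test_that("drift correction preserves within-feature sample rank order", {
  sim <- generate_cohort(small_config(seed = 44, drift_fold = 1.8,
                                      dropout_fraction = 0))
  out <- qc_drift_correct(sim$table, sim$records)
  # correction divides each sample by a per-feature positive curve; ranks
  # across samples may change, but each value keeps its sign and positivity,
  # and a feature with uniform values across samples stays uniform
  expect_true(all(out$table$abund > 0))
  # end-to-end: drift correction reduces QC RSD on drifting data
  qcs <- sim$records$sample_id[sim$records$group == "QC"]
  rsd <- function(m) apply(m[, qcs], 1, function(v) sd(v, na.rm = TRUE) /
                             mean(v, na.rm = TRUE))
  expect_lt(median(rsd(out$table$abund), na.rm = TRUE),
            median(rsd(sim$table$abund), na.rm = TRUE))
})

test_that("drift correction demands enough QCs", {
  labels <- c("TKO", "CTRL", "QC", "QC", "TKO", "CTRL")
  recs <- flat_records(labels)
  m <- matrix(1:12, 2, 6, dimnames = list(c("A", "B"), recs$sample_id))
  expect_error(qc_drift_correct(feature_table(m), recs), ">= 3 QC")
})

test_that("filters only remove features, never alter abundances", {
  sim <- generate_cohort(small_config(seed = 8))
  out <- qc_pipeline(sim$table, sim$records, drift = FALSE)
  kept <- rownames(out$table$abund)
  expect_equal(out$table$abund, sim$table$abund[kept, ])
  expect_length(out$table$provenance, 1 + 3)  # generator + three rules
})
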