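#' Blank (background-signal) filter
#'
#' Removes features whose mean study-sample abundance is below `factor`
#' times the mean abundance in blank injections — such peaks are background
#' signal rather than serum-derived. The boundary keeps the feature
#' (removal requires strictly "less than `factor` times the baseline");
#' features with a zero blank mean are always kept.
#'
#' @param table a [feature_table()].
#' @param records sample metadata (used to find study and blank samples).
#' @param factor fold-over-blank threshold (default 5).
#' @return list with `table` (filtered) and `report` (per-feature ratios and
#'   keep flags, plus the removed count).
#' @export
blank_filter <- function(table, records, factor = 5) {
  blanks <- group_samples(records, "BLANK")
  if (length(blanks) < 1) {
    stop("no blank samples present; skip the blank rule explicitly if intended")
  }
  study <- records$sample_id[is_study(records)]
  study_mean <- rowMeans(table$abund[, study, drop = FALSE], na.rm = TRUE)
  blank_mean <- rowMeans(table$abund[, blanks, drop = FALSE], na.rm = TRUE)
  blank_mean[is.nan(blank_mean)] <- 0
  keep <- blank_mean == 0 | study_mean >= factor * blank_mean
  report <- data.frame(
    feature_id = feature_ids(table),
    study_mean = study_mean, blank_mean = blank_mean,
    blank_ratio = ifelse(blank_mean > 0, study_mean / blank_mean, Inf),
    keep = keep, row.names = NULL
  )
  out <- ft_subset(table, features = which(keep))
  out <- ft_log(out, sprintf("blank_filter(factor=%g): removed %d/%d",
                             factor, sum(!keep), length(keep)))
  list(table = out, report = report, n_removed = sum(!keep))
}

#' QC-presence filter
#'
#' Keeps a feature only if it is present (non-missing and positive) in at
#' least `min_fraction` of the pooled-QC injections; features the instrument
#' cannot reproducibly detect in the pool are unreliable in study samples.
#'
#' @inheritParams blank_filter
#' @param min_fraction minimum detected fraction of QC injections
#'   (default 0.5).
#' @return list with `table`, `report`, `n_removed`.
#' @export
qc_presence_filter <- function(table, records, min_fraction = 0.5) {
  qcs <- group_samples(records, "QC")
  if (length(qcs) < 2) stop("need >= 2 QC samples for the presence filter")
  q <- table$abund[, qcs, drop = FALSE]
  frac <- rowMeans(!is.na(q) & q > 0)
  keep <- frac >= min_fraction
  report <- data.frame(feature_id = feature_ids(table),
                       qc_presence_fraction = frac, keep = keep,
                       row.names = NULL)
  out <- ft_subset(table, features = which(keep))
  out <- ft_log(out, sprintf("qc_presence_filter(min=%g): removed %d/%d",
                             min_fraction, sum(!keep), length(keep)))
  list(table = out, report = report, n_removed = sum(!keep))
}

#' QC relative-standard-deviation filter
#'
#' Keeps a feature only if its RSD (sample standard deviation over mean)
#' across the QC injections is at most `max_rsd`: high QC dispersion means
#' the measurement is not reproducible. Features with fewer than 3 usable QC
#' values cannot be evaluated; they are kept and flagged indeterminate.
#'
#' @inheritParams blank_filter
#' @param max_rsd maximum tolerated RSD (default 0.30).
#' @return list with `table`, `report` (`qc_rsd`, `keep`, `indeterminate`),
#'   `n_removed`.
#' @export
qc_rsd_filter <- function(table, records, max_rsd = 0.30) {
  qcs <- group_samples(records, "QC")
  if (length(qcs) < 3) stop("need >= 3 QC samples for the RSD filter")
  q <- table$abund[, qcs, drop = FALSE]
  n_ok <- rowSums(!is.na(q))
  mu <- rowMeans(q, na.rm = TRUE)
  sdv <- apply(q, 1, stats::sd, na.rm = TRUE)
  rsd <- ifelse(mu > 0, sdv / mu, Inf)
  indeterminate <- n_ok < 3
  keep <- indeterminate | rsd <= max_rsd
  report <- data.frame(feature_id = feature_ids(table), qc_rsd = rsd,
                       indeterminate = indeterminate, keep = keep,
                       row.names = NULL)
  out <- ft_subset(table, features = which(keep))
  out <- ft_log(out, sprintf("qc_rsd_filter(max=%g): removed %d/%d",
                             max_rsd, sum(!keep), length(keep)))
  list(table = out, report = report, n_removed = sum(!keep))
}

#' QC-based injection-order drift correction
#'
#' Corrects slow instrument-response drift using the pooled-QC injections
#' interleaved through the run. Per feature, a smooth curve (LOWESS with
#' span 0.75; simple linear regression when fewer than 5 usable QC points)
#' is fitted to QC abundance versus injection order and normalised to the
#' median QC level; every sample's abundance is divided by the interpolated
#' curve value at its own injection order. The feature's median QC abundance
#' is thereby preserved, and within-feature sample ranks are unchanged.
#' Curve values are interpolated linearly between QC injections and held
#' constant beyond the first/last QC; samples outside the QC span are
#' flagged as extrapolated.
#'
#' @inheritParams blank_filter
#' @param span LOWESS span over the QC points (default 0.75).
#' @return list with `table` (corrected), `report` (per-feature curve range
#'   and an extrapolation flag), `n_removed` (always 0).
#' @export
qc_drift_correct <- function(table, records, span = 0.75) {
  qcs <- group_samples(records, "QC")
  if (length(qcs) < 3) stop("need >= 3 QC samples for drift correction")
  ord <- records$injection_order[match(sample_ids(table), records$sample_id)]
  if (any(is.na(ord))) stop("every sample needs an injection_order")
  qc_ord <- records$injection_order[match(qcs, records$sample_id)]
  study_ord <- records$injection_order[match(
    records$sample_id[is_study(records)], records$sample_id)]
  extrapolated <- any(study_ord < min(qc_ord)) || any(study_ord > max(qc_ord))

  m <- table$abund
  out <- m
  curve_min <- curve_max <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    qv <- m[i, qcs]
    ok <- !is.na(qv) & qv > 0
    if (sum(ok) < 3) next  # cannot fit; leave feature untouched
    xo <- qc_ord[ok]
    yo <- qv[ok]
    o <- order(xo)
    xo <- xo[o]
    yo <- yo[o]
    if (sum(ok) < 5) {
      fit <- stats::lm.fit(cbind(1, xo), yo)
      yhat <- fit$coefficients[1] + fit$coefficients[2] * xo
    } else {
      yhat <- stats::lowess(xo, yo, f = span)$y
    }
    yhat <- pmax(yhat, .Machine$double.eps)
    ref <- stats::median(yo)
    curve <- stats::approx(xo, yhat / ref, xout = ord, rule = 2)$y
    out[i, ] <- m[i, ] / curve
    curve_min[i] <- min(curve)
    curve_max[i] <- max(curve)
  }
  report <- data.frame(feature_id = feature_ids(table),
                       curve_min = curve_min, curve_max = curve_max,
                       extrapolated = extrapolated, row.names = NULL)
  tab <- table
  tab$abund <- out
  tab <- ft_log(tab, sprintf("qc_drift_correct(span=%g)", span))
  list(table = tab, report = report, n_removed = 0L)
}

#' Run the full QC curation chain
#'
#' Drift correction (optional), then blank, QC-presence and QC-RSD filters.
#' The three removal rules are per-feature and independent, so their order
#' does not change the final kept set.
#'
#' @inheritParams blank_filter
#' @param blank_factor,min_fraction,max_rsd rule thresholds.
#' @param drift apply drift correction first (default TRUE).
#' @return list with `table` and a combined `report` list per rule.
#' @export
qc_pipeline <- function(table, records, blank_factor = 5, min_fraction = 0.5,
                        max_rsd = 0.30, drift = TRUE) {
  reports <- list()
  if (drift) {
    dc <- qc_drift_correct(table, records)
    table <- dc$table
    reports$drift <- dc$report
  }
  bf <- blank_filter(table, records, factor = blank_factor)
  reports$blank <- bf$report
  pf <- qc_presence_filter(bf$table, records, min_fraction = min_fraction)
  reports$presence <- pf$report
  rf <- qc_rsd_filter(pf$table, records, max_rsd = max_rsd)
  reports$rsd <- rf$report
  list(table = rf$table, reports = reports,
       n_removed = c(blank = bf$n_removed, presence = pf$n_removed,
                     rsd = rf$n_removed))
}
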