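#' Percent lifetime of a mouse at a sampling point
#'
#' Aligns longitudinal samples across mice with different survival times by
#' normalising age to each animal's own lifespan:
#' `100 * age / lifespan`. For control mice, which do not die of disease
#' during the study, the denominator is the age at their last blood
#' collection, so both groups populate the whole 0-100 range.
#'
#' @param age_weeks age at sampling (weeks); vectorised.
#' @param lifespan_weeks total lifespan, or age at last collection for
#'   controls (weeks).
#' @return Percent lifetime in (0, 100].
#' @export
percent_lifetime <- function(age_weeks, lifespan_weeks) {
  if (any(lifespan_weeks <= 0)) stop("lifespan_weeks must be positive")
  if (any(age_weeks <= 0)) stop("age_weeks must be positive")
  if (any(age_weeks > lifespan_weeks)) {
    stop("age_weeks exceeds lifespan_weeks")
  }
  100 * age_weeks / lifespan_weeks
}

#' Disease-stage bins on the percent-lifetime axis
#'
#' The four HGSC stage bins used throughout: premalignant PRE (20-36
#' %lifetime), tumor onset ET1 (37-60), early tumor ET2 (61-80) and
#' advanced/metastatic AT (81-100). The integer bin labels are realised as
#' half-open real intervals `[20,37) [37,61) [61,81) [81,100]`; values below
#' 20 (possible for long-lived controls' earliest samples) map to PRE.
#'
#' @return Named list of `c(lower, upper)` bounds per stage, in order.
#' @export
stage_bins <- function() {
  list(PRE = c(0, 37), ET1 = c(37, 61), ET2 = c(61, 81), AT = c(81, 100))
}

#' Assign a disease stage from percent lifetime
#'
#' @param pct_lifetime numeric in \[0, 100]; vectorised.
#' @return Character vector of stage labels (PRE/ET1/ET2/AT).
#' @seealso [stage_bins()]
#' @export
assign_stage <- function(pct_lifetime) {
  if (any(pct_lifetime < 0 | pct_lifetime > 100, na.rm = TRUE)) {
    stop("pct_lifetime must lie in [0, 100]")
  }
  labs <- names(stage_bins())
  labs[findInterval(pct_lifetime, c(0, 37, 61, 81), rightmost.closed = FALSE)]
}

# sample ids of study samples falling in a %lifetime bin.
# bin: either a stage label or c(lower, upper); upper edge closed only at 100.
samples_in_bin <- function(records, bin) {
  if (is.character(bin)) {
    b <- stage_bins()[[bin]]
    if (is.null(b)) stop("unknown stage bin: ", bin)
    bin <- b
  }
  pct <- records$pct_lifetime
  upper_closed <- bin[2] >= 100
  inside <- !is.na(pct) & pct >= bin[1] &
    (if (upper_closed) pct <= bin[2] else pct < bin[2])
  records$sample_id[inside & is_study(records)]
}

#' Log2 fold change of one feature within a %lifetime bin
#'
#' The trajectory primitive: `log2(mean TKO / mean CTRL)` over the study
#' samples whose percent lifetime falls in the bin, with a delta-method
#' standard error `(1/ln 2) * sqrt(cv_TKO^2/n_TKO + cv_CTRL^2/n_CTRL)` where
#' `cv` is each group's within-bin coefficient of variation.
#'
#' @param table a [feature_table()] (post-QC abundances).
#' @param records sample metadata.
#' @param feature_id feature to evaluate.
#' @param bin stage label (see [stage_bins()]) or numeric `c(lower, upper)`.
#' @return list with `log2fc`, `se`, `n_tko`, `n_ctrl`, `bin`.
#' @export
bin_log2_fold_change <- function(table, records, feature_id, bin) {
  ids <- samples_in_bin(records, bin)
  recs <- records[match(ids, records$sample_id), , drop = FALSE]
  vals <- table$abund[feature_id, ids]
  grp <- recs$group
  x <- vals[grp == "TKO" & !is.na(vals)]
  y <- vals[grp == "CTRL" & !is.na(vals)]
  if (length(x) < 1 || length(y) < 1) {
    stop("bin has an empty group for feature ", feature_id)
  }
  my <- mean(y)
  if (my == 0) stop("zero control mean in bin for feature ", feature_id)
  mx <- mean(x)
  cv2 <- function(v) if (length(v) < 2) 0 else stats::var(v) / mean(v)^2
  se <- sqrt(cv2(x) / length(x) + cv2(y) / length(y)) / log(2)
  list(
    log2fc = log2(mx / my), se = se,
    n_tko = length(x), n_ctrl = length(y),
    bin = if (is.character(bin)) bin else sprintf("[%g,%g]", bin[1], bin[2])
  )
}

#' Per-class log2 fold-change trajectory
#'
#' For a lipid class, each sample's class score is the mean abundance over
#' the class's statistically significant features; the trajectory is then the
#' per-bin log2 fold change of those scores (TKO over CTRL), by default over
#' the four disease-stage bins.
#'
#' @param table a [feature_table()].
#' @param annotations data.frame with at least `feature_id` and `lipid_class`.
#' @param records sample metadata.
#' @param lipid_class class to trace.
#' @param significant_ids feature ids that passed screening (the class score
#'   averages only over these).
#' @param bins list of bins: stage labels and/or numeric bounds; default the
#'   four stages. `fine_bins()` gives fixed-width 5 %lifetime bins instead.
#' @return data.frame with one row per bin that has both groups represented
#'   (bins with an empty group are dropped with a warning).
#' @export
class_trajectory <- function(table, annotations, records, lipid_class,
                             significant_ids, bins = as.list(names(stage_bins()))) {
  feats <- intersect(
    annotations$feature_id[annotations$lipid_class == lipid_class],
    intersect(significant_ids, feature_ids(table))
  )
  if (length(feats) == 0) {
    warning("no significant features in class ", lipid_class)
    return(data.frame())
  }
  score <- colMeans(table$abund[feats, , drop = FALSE], na.rm = TRUE)
  score_tab <- feature_table(matrix(score, nrow = 1,
                                    dimnames = list("class_score", names(score))))
  rows <- lapply(bins, function(b) {
    pt <- tryCatch(bin_log2_fold_change(score_tab, records, "class_score", b),
                   error = function(e) NULL)
    if (is.null(pt)) return(NULL)
    data.frame(lipid_class = lipid_class, bin = pt$bin, log2fc = pt$log2fc,
               se = pt$se, n_tko = pt$n_tko, n_ctrl = pt$n_ctrl)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) warning(dropped, " bin(s) dropped (empty group)")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Fixed-width fine bins on the percent-lifetime axis
#'
#' @param width bin width in %lifetime units (default 5).
#' @param from,to axis range (default 20 to 100).
#' @return list of `c(lower, upper)` bins.
#' @export
fine_bins <- function(width = 5, from = 20, to = 100) {
  lo <- seq(from, to - width, by = width)
  lapply(lo, function(l) c(l, l + width))
}
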