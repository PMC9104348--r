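#' Compute all pairwise feature ratios
#'
#' Builds one ratio feature per unordered pair of input features, computed
#' per sample on the raw (post-QC) abundance scale. Orientation is the
#' lexicographic feature-id order; entries with a missing or zero
#' denominator are missing. For `m` features this yields `choose(m, 2)`
#' ratios.
#'
#' @param table a [feature_table()].
#' @param feature_ids features to pair (>= 2); default all.
#' @return A [feature_table()] of ratio features named
#'   `"<numerator>/<denominator>"`.
#' @export
all_pair_ratios <- function(table, feature_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- rownames(table$abund)
  feature_ids <- sort(as.character(feature_ids))
  if (length(feature_ids) < 2) stop("need >= 2 features to form ratios")
  m <- table$abund[feature_ids, , drop = FALSE]
  pairs <- utils::combn(feature_ids, 2)
  num <- m[pairs[1, ], , drop = FALSE]
  den <- m[pairs[2, ], , drop = FALSE]
  den[!is.na(den) & den == 0] <- NA_real_
  ratio <- num / den
  rownames(ratio) <- paste(pairs[1, ], pairs[2, ], sep = "/")
  ft <- feature_table(ratio)
  ft$provenance <- c(table$provenance,
                     sprintf("all_pair_ratios(%d features -> %d ratios)",
                             length(feature_ids), nrow(ratio)))
  ft
}

#' Rank ratio features by Welch p-value
#'
#' G-log transforms and autoscales the ratio matrix, tests each ratio
#' between the two classes with Welch's t-test, and returns the `top_k`
#' ratios by ascending p. Because the g-log is monotone and autoscaling is
#' affine, inverting a ratio leaves |t| unchanged, so the lexicographic
#' orientation of [all_pair_ratios()] does not affect the ranking.
#'
#' @param ratio_table output of [all_pair_ratios()].
#' @param records sample metadata (TKO/CTRL study samples are used).
#' @param top_k number of ratios to return (default 20; capped with a
#'   warning when fewer ratios exist).
#' @return data.frame of ranked ratios: `ratio`, `numerator`, `denominator`,
#'   `t`, `p`.
#' @export
rank_ratios <- function(ratio_table, records, top_k = 20) {
  ids <- records$sample_id[is_study(records)]
  ids <- intersect(ids, sample_ids(ratio_table))
  recs <- records[match(ids, records$sample_id), , drop = FALSE]
  if (length(unique(recs$group)) < 2) stop("both classes must be present")
  m <- ratio_table$abund[, ids, drop = FALSE]
  g <- glog(m)
  gs <- t(autoscale(t(g))$X)  # per-ratio autoscaling across samples
  res <- welch_t_matrix(gs, which(recs$group == "TKO"),
                        which(recs$group == "CTRL"))
  res <- res[!is.na(res$p), , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  if (top_k > nrow(res)) {
    warning("top_k exceeds number of testable ratios; returning all")
    top_k <- nrow(res)
  }
  res <- res[seq_len(top_k), , drop = FALSE]
  parts <- strsplit(res$feature_id, "/", fixed = TRUE)
  data.frame(
    ratio = res$feature_id,
    numerator = vapply(parts, `[`, character(1), 1),
    denominator = vapply(parts, `[`, character(1), 2),
    t = res$t, p = res$p, row.names = NULL
  )
}

# stratified fold ids preserving class balance, deterministic given the RNG
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    folds[i] <- (sample(seq_along(i)) - 1L) %% n_folds + 1L
  }
  folds
}

#' Cross-validated logistic-regression evaluation of one ratio
#'
#' Evaluates a single ratio's diagnostic value: the g-log/autoscaled ratio
#' enters a univariate logistic regression under stratified k-fold CV;
#' pooled out-of-fold probabilities give the ROC AUC and the
#' sensitivity/specificity at the Youden-optimal pooled threshold. 95%
#' confidence intervals come from a percentile bootstrap over samples
#' (resampling the pooled out-of-fold predictions). Ratios with AUC below
#' 0.5 are reported in the flipped orientation (AUC >= 0.5 by convention).
#'
#' @param ratio numeric vector of per-sample ratio values (raw scale).
#' @param labels class labels ("TKO"/"CTRL" or +1/-1); TKO is the positive
#'   class.
#' @param n_folds stratified folds (default 10).
#' @param n_boot bootstrap resamples for the CIs (default 2000; 0 disables
#'   the bootstrap and returns `NA` CIs).
#' @param seed RNG seed for fold assignment and bootstrap.
#' @return list with `auc`, `sensitivity`, `specificity`, each with
#'   `*_ci` = c(lower, upper), plus `threshold`, `flipped`, `degenerate`.
#' @export
cv_logistic_eval <- function(ratio, labels, n_folds = 10, n_boot = 2000,
                             seed = 1) {
  y <- class_coding(labels)
  ok <- !is.na(ratio)
  ratio <- ratio[ok]
  y <- y[ok]
  n <- length(y)
  if (n < n_folds) stop("need at least n_folds samples")
  pos <- y == 1

  degenerate <- stats::sd(ratio) == 0
  if (degenerate) {
    return(list(auc = 0.5, auc_ci = c(NA, NA), sensitivity = NA,
                sensitivity_ci = c(NA, NA), specificity = NA,
                specificity_ci = c(NA, NA), threshold = NA,
                flipped = FALSE, degenerate = TRUE))
  }
  x <- drop(autoscale(matrix(glog(ratio), ncol = 1))$X)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  folds <- stratified_folds(y, n_folds)
  prob <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- stats::glm(pos[tr] ~ x[tr], family = stats::binomial())
    eta <- fit$coefficients[1] + fit$coefficients[2] * x[!tr]
    prob[!tr] <- stats::plogis(eta)
  }

  roc_metrics <- function(prob, pos) {
    r <- pROC::roc(response = pos, predictor = prob, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    auc <- as.numeric(pROC::auc(r))
    j <- r$sensitivities + r$specificities - 1
    k <- which.max(j)
    list(auc = auc, sens = r$sensitivities[k], spec = r$specificities[k],
         thr = r$thresholds[k])
  }
  obs <- roc_metrics(prob, pos)
  flipped <- obs$auc < 0.5
  if (flipped) {
    prob <- 1 - prob
    obs <- roc_metrics(prob, pos)
  }

  cis <- list(auc = c(NA, NA), sens = c(NA, NA), spec = c(NA, NA))
  if (n_boot > 0) {
    stats_b <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(pos[i])) < 2) next
      m <- roc_metrics(prob[i], pos[i])
      # sens/spec at the fixed pooled threshold, so the CI speaks to the
      # reported operating point rather than a refit one
      sens_b <- mean(prob[i][pos[i]] >= obs$thr)
      spec_b <- mean(prob[i][!pos[i]] < obs$thr)
      stats_b[b, ] <- c(m$auc, sens_b, spec_b)
    }
    qs <- apply(stats_b, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    cis <- list(auc = qs[, 1], sens = qs[, 2], spec = qs[, 3])
  }
  list(auc = obs$auc, auc_ci = unname(cis$auc),
       sensitivity = obs$sens, sensitivity_ci = unname(cis$sens),
       specificity = obs$spec, specificity_ci = unname(cis$spec),
       threshold = obs$thr, flipped = flipped, degenerate = FALSE)
}

#' Screen, rank and evaluate ratio biomarkers
#'
#' Convenience chain: [all_pair_ratios()] on the given features,
#' [rank_ratios()] for the top `top_k` by Welch p, then
#' [cv_logistic_eval()] on each, producing a report shaped like a biomarker
#' table (ratio, p, AUC and CIs, sensitivity, specificity).
#'
#' @inheritParams all_pair_ratios
#' @inheritParams rank_ratios
#' @inheritParams cv_logistic_eval
#' @param records sample metadata.
#' @return data.frame, one row per evaluated ratio.
#' @export
ratio_biomarker_screen <- function(table, records, feature_ids = NULL,
                                   top_k = 20, n_folds = 10, n_boot = 2000,
                                   seed = 1) {
  ratios <- all_pair_ratios(table, feature_ids)
  ranked <- rank_ratios(ratios, records, top_k = top_k)
  ids <- records$sample_id[is_study(records)]
  labels <- records$group[match(ids, records$sample_id)]
  rows <- lapply(seq_len(nrow(ranked)), function(i) {
    ev <- cv_logistic_eval(ratios$abund[ranked$ratio[i], ids], labels,
                           n_folds = n_folds, n_boot = n_boot,
                           seed = seed + i)
    data.frame(
      ratio = ranked$ratio[i], p = ranked$p[i],
      auc = ev$auc, auc_lo = ev$auc_ci[1], auc_hi = ev$auc_ci[2],
      sensitivity = ev$sensitivity, sens_lo = ev$sensitivity_ci[1],
      sens_hi = ev$sensitivity_ci[2],
      specificity = ev$specificity, spec_lo = ev$specificity_ci[1],
      spec_hi = ev$specificity_ci[2], flipped = ev$flipped
    )
  })
  do.call(rbind, rows)
}
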