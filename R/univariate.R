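#' Welch's two-sample t-test (vectorised)
#'
#' Two-tailed Welch t-test with Satterthwaite degrees of freedom, the
#' screening test applied to every feature. Implemented directly from the
#' textbook formulas so that thousands of features can be tested in one
#' vectorised pass (see [welch_t_matrix()]); agrees with
#' `stats::t.test(var.equal = FALSE)` to machine precision.
#'
#' @param x,y numeric vectors (missing values dropped), each with >= 2 values.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 non-missing values")
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (v1 + v2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  s1 <- v1 / n1
  s2 <- v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Welch's t-test for every row of a matrix
#'
#' @param m numeric matrix, features in rows.
#' @param idx_x,idx_y column indices (or names) of the two groups.
#' @return data.frame with `feature_id`, `t`, `df`, `p`; rows with fewer than
#'   2 usable values in a group or zero combined variance get `NA` statistics
#'   (`p = 1` when both groups are constant and equal).
#' @export
welch_t_matrix <- function(m, idx_x, idx_y) {
  X <- m[, idx_x, drop = FALSE]
  Y <- m[, idx_y, drop = FALSE]
  n1 <- rowSums(!is.na(X))
  n2 <- rowSums(!is.na(Y))
  m1 <- rowMeans(X, na.rm = TRUE)
  m2 <- rowMeans(Y, na.rm = TRUE)
  v1 <- (rowSums(X^2, na.rm = TRUE) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(Y^2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0)  # guard tiny negative values from cancellation
  v2 <- pmax(v2, 0)
  s1 <- v1 / n1
  s2 <- v2 / n2
  tt <- (m1 - m2) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  usable <- n1 >= 2 & n2 >= 2
  degenerate <- usable & (v1 + v2) == 0
  tt[!usable] <- NA_real_
  df[!usable] <- NA_real_
  p[!usable] <- NA_real_
  tt[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  data.frame(feature_id = rownames(m), t = tt, df = df, p = p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1] (`NA` allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen features by Welch's t-test with FDR control
#'
#' Runs Welch's t-test (TKO vs CTRL) per feature on the chosen sample
#' subset, adjusts with Benjamini-Hochberg, and returns the features with
#' `q < alpha`. The screening treats longitudinal samples as independent
#' observations; set `per_mouse = TRUE` to first average each mouse's samples
#' within the window (a stricter option the default analysis does not use).
#'
#' @param table a [feature_table()].
#' @param records sample metadata.
#' @param alpha FDR level (default 0.05).
#' @param window optional `c(lower, upper)` %lifetime window to subset
#'   study samples (upper edge closed at 100 only).
#' @param per_mouse average samples per mouse before testing.
#' @return list with `significant` (feature ids) and `results` (data.frame
#'   feature_id, t, df, p, q).
#' @export
select_significant <- function(table, records, alpha = 0.05, window = NULL,
                               per_mouse = FALSE) {
  ids <- if (is.null(window)) {
    records$sample_id[is_study(records)]
  } else {
    samples_in_bin(records, window)
  }
  if (length(ids) == 0) stop("no study samples in the requested window")
  recs <- records[match(ids, records$sample_id), , drop = FALSE]
  m <- table$abund[, ids, drop = FALSE]
  grp <- recs$group
  if (per_mouse) {
    mouse <- recs$mouse_id
    agg <- vapply(split(seq_along(ids), mouse), function(j) {
      rowMeans(m[, j, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(m)))
    if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(m))
    rownames(agg) <- rownames(m)
    grp <- vapply(split(grp, mouse), `[`, character(1), 1)
    m <- agg
  }
  if (sum(grp == "TKO") < 2 || sum(grp == "CTRL") < 2) {
    stop("need >= 2 samples per group after subsetting")
  }
  res <- welch_t_matrix(m, which(grp == "TKO"), which(grp == "CTRL"))
  res$q <- bh_adjust(res$p)
  list(
    significant = res$feature_id[!is.na(res$q) & res$q < alpha],
    results = res
  )
}
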