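#' Autoscale a samples x features matrix
#'
#' Centres each column to mean 0 and scales to unit sample standard
#' deviation, the standard pretreatment before PLS-type modelling.
#' Zero-variance columns are set to 0 and flagged.
#'
#' @param X numeric matrix, samples in rows.
#' @param means,scales optionally reapply a stored scaling (e.g. a training
#'   fold's) instead of estimating from `X`.
#' @return list with `X` (scaled), `means`, `scales`, `zero_variance`
#'   (logical per column).
#' @export
autoscale <- function(X, means = NULL, scales = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2 && is.null(means)) stop("autoscale needs >= 2 rows")
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  if (is.null(scales)) scales <- apply(X, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(scales) | scales == 0
  sc <- scales
  sc[zero] <- 1
  Xs <- sweep(sweep(X, 2, means, "-"), 2, sc, "/")
  Xs[, zero] <- 0
  list(X = Xs, means = means, scales = scales, zero_variance = zero)
}

#' Generalised logarithm transform
#'
#' `glog(x) = log2((x + sqrt(x^2 + lambda)) / 2)`, a variance-stabilising
#' transform for abundance data that behaves like log2 for large `x` but
#' remains finite at 0. With `lambda = 0` it reduces exactly to log2.
#'
#' @param x non-negative numeric vector or matrix.
#' @param lambda transform parameter; default is the square of the smallest
#'   positive value in `x`.
#' @return Transformed object of the same shape.
#' @export
glog <- function(x, lambda = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop("glog requires non-negative input")
  if (is.null(lambda)) {
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) == 0) stop("cannot choose lambda: no positive values")
    lambda <- min(pos)^2
  }
  if (lambda < 0) stop("lambda must be non-negative")
  log2((x + sqrt(x^2 + lambda)) / 2)
}

#' Principal component analysis
#'
#' Thin wrapper around `stats::prcomp` on an already centred/autoscaled
#' matrix, returning scores, loadings and explained-variance fractions.
#'
#' @param X numeric matrix, samples in rows (centred or autoscaled).
#' @param n_components number of components (truncated to the rank with a
#'   warning if larger).
#' @return list with `scores`, `loadings`, `explained` (fractions).
#' @export
pca <- function(X, n_components = 2) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  r <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (n_components > r) {
    warning("n_components exceeds rank; truncated to ", r)
    n_components <- r
  }
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[k])
}

# Encode TKO/CTRL labels as +1/-1; accepts an already numeric +-1 vector.
class_coding <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must be coded +1/-1")
    return(y)
  }
  y <- as.character(y)
  bad <- setdiff(unique(y), c("TKO", "CTRL"))
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  ifelse(y == "TKO", 1, -1)
}

#' Fit an orthogonal PLS-DA model
#'
#' Two-class discriminant model in the O-PLS style: `n_orth`
#' orthogonal-signal-correction components (structured variation orthogonal
#' to the class variable) are estimated and removed iteratively, then a
#' single predictive PLS component is fitted on the filtered matrix.
#' With `n_orth = 0` the model is exactly a 1-latent-variable PLS-DA.
#' Class coding is TKO = +1, CTRL = -1; the input matrix is autoscaled
#' internally and the scaling is stored for prediction.
#'
#' @param X numeric matrix, samples in rows.
#' @param y class labels ("TKO"/"CTRL" or +1/-1); both classes required.
#' @param n_orth number of orthogonal components (>= 0).
#' @param scale autoscale `X` (default TRUE; set FALSE if pre-scaled).
#' @return An object of class `opls_model` with predictive weights/loadings
#'   (`w`, `p`, `q`), orthogonal components (`w_orth`, `p_orth`), training
#'   scores `t_pred` and `t_orth`, and the stored scaling.
#' @export
opls_da_fit <- function(X, y, n_orth = 1, scale = TRUE) {
  X <- as.matrix(X)
  yy <- class_coding(y)
  if (length(unique(yy)) < 2) stop("both classes must be present")
  if (n_orth < 0) stop("n_orth must be >= 0")
  sc <- if (scale) autoscale(X) else
    list(X = X, means = rep(0, ncol(X)), scales = rep(1, ncol(X)),
         zero_variance = rep(FALSE, ncol(X)))
  Xf <- sc$X
  y_mean <- mean(yy)
  yc <- yy - y_mean

  normv <- function(v) v / sqrt(sum(v^2))
  w <- normv(drop(crossprod(Xf, yc)) / sum(yc^2))
  W_orth <- P_orth <- NULL
  T_orth <- NULL
  if (n_orth > 0) {
    for (k in seq_len(n_orth)) {
      tt <- drop(Xf %*% w)
      p <- drop(crossprod(Xf, tt)) / sum(tt^2)
      wo <- p - drop(crossprod(w, p)) * w
      if (sqrt(sum(wo^2)) < 1e-12) break  # no orthogonal variation left
      wo <- normv(wo)
      to <- drop(Xf %*% wo)
      po <- drop(crossprod(Xf, to)) / sum(to^2)
      Xf <- Xf - tcrossprod(to, po)
      W_orth <- cbind(W_orth, wo)
      P_orth <- cbind(P_orth, po)
      T_orth <- cbind(T_orth, to)
      w <- normv(drop(crossprod(Xf, yc)) / sum(yc^2))
    }
  }
  t_pred <- drop(Xf %*% w)
  p_pred <- drop(crossprod(Xf, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  structure(list(
    w = w, p = p_pred, q = q, y_mean = y_mean,
    w_orth = W_orth, p_orth = P_orth,
    t_pred = t_pred, t_orth = T_orth,
    n_orth = if (is.null(W_orth)) 0L else ncol(W_orth),
    means = sc$means, scales = sc$scales, zero_variance = sc$zero_variance,
    feature_names = colnames(X)
  ), class = "opls_model")
}

#' Predict classes from an oPLS-DA model
#'
#' Applies the stored autoscaling, removes the model's orthogonal
#' components, projects onto the predictive component and thresholds the
#' predicted class variable at 0. A predicted value of exactly 0 is assigned
#' CTRL (deterministic tie-break).
#'
#' @param model an `opls_model` from [opls_da_fit()].
#' @param X_new matrix with the model's feature set (samples in rows).
#' @return list with `scores` (predictive component), `y_hat` (continuous),
#'   `class` (+1 TKO / -1 CTRL).
#' @export
opls_da_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$w)) {
    stop("feature mismatch: model has ", length(model$w), " features, X_new ",
         ncol(X_new))
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$feature_names)) {
    stop("feature names of X_new do not match the model")
  }
  Xs <- autoscale(X_new, means = model$means,
                  scales = ifelse(model$zero_variance, 1, model$scales))$X
  Xs[, model$zero_variance] <- 0
  if (model$n_orth > 0) {
    for (k in seq_len(model$n_orth)) {
      to <- drop(Xs %*% model$w_orth[, k])
      Xs <- Xs - tcrossprod(to, model$p_orth[, k])
    }
  }
  t_pred <- drop(Xs %*% model$w)
  y_hat <- t_pred * model$q + model$y_mean
  cls <- ifelse(y_hat > 0, 1, -1)
  list(scores = t_pred, y_hat = y_hat, class = cls)
}

# Venetian-blind fold ids: sample i (1-based, in the given fixed order) goes
# to fold ((i - 1) %% n_folds) + 1.
venetian_folds <- function(n, n_folds) ((seq_len(n) - 1L) %% n_folds) + 1L

#' Venetian-blind cross-validation of an oPLS-DA model
#'
#' Interleaved k-fold CV: in the fixed sample order (by convention the
#' acquisition/injection order), every `n_folds`-th sample lands in the same
#' fold. Scaling and the model are refit within each training split; the
#' held-out predictions give sensitivity (TKO recall), specificity (CTRL
#' recall), accuracy, and RMSECV of the continuous class variable.
#'
#' @param X samples x features matrix in the fixed order.
#' @param y class labels in the same order.
#' @param n_orth orthogonal components of the model.
#' @param n_folds number of folds (default 10); `n_folds = nrow(X)` is
#'   leave-one-out.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `rmsecv`,
#'   `predicted` (+1/-1 per sample), `y_hat`, `folds`, `n_folds`.
#' @export
venetian_blind_cv <- function(X, y, n_orth = 1, n_folds = 10) {
  X <- as.matrix(X)
  yy <- class_coding(y)
  n <- nrow(X)
  if (n_folds > n) stop("n_folds exceeds number of samples")
  folds <- venetian_folds(n, n_folds)
  y_hat <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(yy[tr])) < 2) {
      stop("training split of fold ", f,
           " contains a single class; reorder samples or reduce folds")
    }
    model <- opls_da_fit(X[tr, , drop = FALSE], yy[tr], n_orth = n_orth)
    y_hat[!tr] <- opls_da_predict(model, X[!tr, , drop = FALSE])$y_hat
  }
  pred <- ifelse(y_hat > 0, 1, -1)
  sens <- mean(pred[yy == 1] == 1)
  spec <- mean(pred[yy == -1] == -1)
  acc <- mean(pred == yy)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       rmsecv = sqrt(mean((yy - y_hat)^2)), predicted = pred, y_hat = y_hat,
       folds = folds, n_folds = n_folds)
}

# Between-class over within-class sum of squares of a score vector.
bw_statistic <- function(scores, y) {
  y <- class_coding(y)
  mu <- mean(scores)
  B <- 0
  W <- 0
  for (cl in unique(y)) {
    s <- scores[y == cl]
    B <- B + length(s) * (mean(s) - mu)^2
    W <- W + sum((s - mean(s))^2)
  }
  B / W
}

#' Permutation test of class separation
#'
#' Guards an oPLS-DA model against overfitting: the group-separation
#' statistic is the between-class to within-class sum-of-squares ratio (B/W)
#' of the predictive scores of a model refit on the given labels. Class
#' labels are permuted uniformly at random `n_perm` times (class counts are
#' preserved by construction) and the p-value is
#' `(1 + #\{permuted B/W >= observed\}) / (1 + n_perm)`.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param n_orth orthogonal components of the refit model.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with `observed` (B/W), `p`, `n_perm`, `permuted` (statistics).
#' @export
permutation_test <- function(X, y, n_orth = 1, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- as.matrix(X)
  yy <- class_coding(y)
  fit_stat <- function(labels) {
    m <- opls_da_fit(X, labels, n_orth = n_orth)
    bw_statistic(m$t_pred, labels)
  }
  observed <- fit_stat(yy)
  perm <- numeric(n_perm)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_len(n_perm)) perm[b] <- fit_stat(sample(yy))
  list(observed = observed,
       p = (1 + sum(perm >= observed)) / (1 + n_perm),
       n_perm = n_perm, permuted = perm,
       statistic = "between/within sum-of-squares of predictive scores")
}
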