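#' Multi-component PLS1 regression (NIPALS)
#'
#' Internal workhorse for the GA fitness and for oPLS-DA reduction checks:
#' fits up to `n_lv` latent variables of a univariate-response PLS model on
#' an autoscaled matrix and centred response.
#'
#' @param X samples x features matrix (autoscaled by the caller).
#' @param y centred numeric response.
#' @param n_lv number of latent variables.
#' @return list with weight (`W`), loading (`P`) and regression (`Q`)
#'   coefficients per component.
#' @keywords internal
pls1_fit <- function(X, y, n_lv) {
  p <- ncol(X)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  Xd <- X
  yd <- y
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1), drop = FALSE]
                      P <- P[, seq_len(a - 1), drop = FALSE]
                      Q <- Q[seq_len(a - 1)]; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    ss <- sum(tt^2)
    pp <- drop(crossprod(Xd, tt)) / ss
    qq <- sum(yd * tt) / ss
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qq * tt
    W[, a] <- w
    P[, a] <- pp
    Q[a] <- qq
  }
  list(W = W, P = P, Q = Q)
}

# Predictions of a pls1_fit model for 1..A components; returns n x A matrix.
pls1_predict_all <- function(fit, X) {
  A <- length(fit$Q)
  out <- matrix(0, nrow(X), max(A, 1))
  if (A == 0) return(out)
  Xd <- X
  acc <- numeric(nrow(X))
  for (a in seq_len(A)) {
    tt <- drop(Xd %*% fit$W[, a])
    acc <- acc + fit$Q[a] * tt
    out[, a] <- acc
    Xd <- Xd - tcrossprod(tt, fit$P[, a])
  }
  out
}

#' Venetian-blind RMSECV of a PLS1 discriminant model
#'
#' The GA fitness primitive: for each latent-variable count 1..`max_lv`,
#' computes the root-mean-square error of cross-validated prediction of the
#' +-1 class variable under interleaved (venetian-blind) folds, refitting
#' autoscaling and centring within each training split.
#'
#' @param X samples x features matrix (raw scale).
#' @param y class labels.
#' @param max_lv maximum latent variables (default 3).
#' @param n_folds folds (default 10, capped at `nrow(X)`).
#' @return list with `rmsecv` (vector over LV counts), `best_lv`,
#'   `best_rmsecv`.
#' @export
pls_rmsecv <- function(X, y, max_lv = 3, n_folds = 10) {
  X <- as.matrix(X)
  yy <- class_coding(y)
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- venetian_folds(n, n_folds)
  max_lv <- min(max_lv, ncol(X))
  yhat <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    sc <- autoscale(X[tr, , drop = FALSE])
    ym <- mean(yy[tr])
    fit <- pls1_fit(sc$X, yy[tr] - ym, max_lv)
    Xte <- autoscale(X[!tr, , drop = FALSE], means = sc$means,
                     scales = ifelse(sc$zero_variance, 1, sc$scales))$X
    Xte[, sc$zero_variance] <- 0
    pred <- pls1_predict_all(fit, Xte) + ym
    A <- ncol(pred)
    yhat[!tr, seq_len(A)] <- pred
    if (A < max_lv) yhat[!tr, (A + 1):max_lv] <- pred[, A]
  }
  rmse <- sqrt(colMeans((yhat - yy)^2))
  list(rmsecv = rmse, best_lv = which.min(rmse), best_rmsecv = min(rmse))
}

#' Default configuration for GA feature selection
#'
#' @param population_size even chromosome count per generation (default 64).
#' @param max_generations generation cap (default 100).
#' @param mutation_rate per-bit flip probability (default 0.005).
#' @param initial_inclusion_prob per-feature inclusion probability in the
#'   initial population (default 0.15).
#' @param crossover "single" or "double" point (default "double").
#' @param max_latent_variables PLS components tried per fitness evaluation
#'   (default 3).
#' @param cv_folds venetian-blind folds for the fitness (default 10).
#' @param convergence_fraction stop when this fraction of the population is
#'   identical to the best chromosome (default 0.5).
#' @param max_features optional cap on panel size (default `Inf`, i.e. none).
#' @param seed RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 64, max_generations = 100,
                      mutation_rate = 0.005, initial_inclusion_prob = 0.15,
                      crossover = c("double", "single"),
                      max_latent_variables = 3, cv_folds = 10,
                      convergence_fraction = 0.5, max_features = Inf,
                      seed = 1) {
  crossover <- match.arg(crossover)
  if (population_size < 2) stop("population_size must be >= 2")
  if (population_size %% 2 != 0) stop("population_size must be even")
  stopifnot(mutation_rate > 0, mutation_rate < 1,
            initial_inclusion_prob > 0, initial_inclusion_prob < 1,
            convergence_fraction > 0, convergence_fraction <= 1)
  structure(list(
    population_size = population_size, max_generations = max_generations,
    mutation_rate = mutation_rate,
    initial_inclusion_prob = initial_inclusion_prob, crossover = crossover,
    max_latent_variables = max_latent_variables, cv_folds = cv_folds,
    convergence_fraction = convergence_fraction, max_features = max_features,
    seed = seed
  ), class = "ga_config")
}

#' Genetic-algorithm feature selection minimising PLS RMSECV
#'
#' Evolves binary feature-inclusion chromosomes by tournament selection,
#' crossover and bitwise mutation. A chromosome's fitness is the minimum
#' venetian-blind RMSECV over 1..`max_latent_variables` PLS components on
#' the autoscaled selected submatrix; lower is better. The best chromosome
#' ever seen always survives (elitism), so the fitness trace is monotone
#' non-increasing. All-zero chromosomes have fitness `+Inf`. Fully
#' deterministic given the config seed.
#'
#' @param X samples x features matrix (raw scale), feature names as columns.
#' @param y class labels.
#' @param config a [ga_config()].
#' @return list of class `ga_result` with `selected` (feature names),
#'   `selected_idx`, `best_rmsecv`, `best_lv`, `trace` (best fitness per
#'   generation), `generations`, `converged`, `config`.
#' @export
ga_feature_select <- function(X, y, config = ga_config()) {
  X <- as.matrix(X)
  yy <- class_coding(y)
  p <- ncol(X)
  if (p < 2) stop("need >= 2 features")
  np <- config$population_size

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  fitness_of <- function(chrom) {
    k <- sum(chrom)
    if (k == 0 || k > config$max_features) return(Inf)
    pls_rmsecv(X[, chrom, drop = FALSE], yy,
               max_lv = config$max_latent_variables,
               n_folds = config$cv_folds)$best_rmsecv
  }

  pop <- matrix(stats::runif(np * p) < config$initial_inclusion_prob, np, p)
  # guarantee at least one gene per initial chromosome
  empty <- rowSums(pop) == 0
  if (any(empty)) pop[cbind(which(empty), sample.int(p, sum(empty), replace = TRUE))] <- TRUE

  fit <- apply(pop, 1, fitness_of)
  best_idx <- which.min(fit)
  best_chrom <- pop[best_idx, ]
  best_fit <- fit[best_idx]
  trace <- numeric(0)
  converged <- FALSE
  gen <- 0L

  while (gen < config$max_generations) {
    gen <- gen + 1L
    trace[gen] <- best_fit
    same <- mean(apply(pop, 1, function(ch) all(ch == best_chrom)))
    if (same >= config$convergence_fraction) { converged <- TRUE; break }

    # tournament selection (size 2)
    pick <- function() {
      ij <- sample.int(np, 2)
      if (fit[ij[1]] <= fit[ij[2]]) ij[1] else ij[2]
    }
    children <- matrix(FALSE, np, p)
    for (m in seq_len(np / 2)) {
      a <- pop[pick(), ]
      b <- pop[pick(), ]
      if (config$crossover == "single" || p < 3) {
        cut <- sample.int(p - 1, 1)
        c1 <- c(a[1:cut], b[(cut + 1):p])
        c2 <- c(b[1:cut], a[(cut + 1):p])
      } else {
        cuts <- sort(sample.int(p - 1, 2))
        mid <- (cuts[1] + 1):cuts[2]
        c1 <- a; c1[mid] <- b[mid]
        c2 <- b; c2[mid] <- a[mid]
      }
      children[2 * m - 1, ] <- c1
      children[2 * m, ] <- c2
    }
    flips <- matrix(stats::runif(np * p) < config$mutation_rate, np, p)
    children <- xor(children, flips)
    children[1, ] <- best_chrom  # elitism
    pop <- children
    fit <- apply(pop, 1, fitness_of)
    gi <- which.min(fit)
    if (fit[gi] < best_fit) {
      best_fit <- fit[gi]
      best_chrom <- pop[gi, ]
    }
  }

  sel <- which(best_chrom)
  best_cv <- pls_rmsecv(X[, sel, drop = FALSE], yy,
                        max_lv = config$max_latent_variables,
                        n_folds = config$cv_folds)
  structure(list(
    selected = if (!is.null(colnames(X))) colnames(X)[sel] else as.character(sel),
    selected_idx = sel,
    best_rmsecv = best_fit, best_lv = best_cv$best_lv,
    trace = trace, generations = gen, converged = converged,
    config = config
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d features selected, RMSECV %.4f (%d LV), %d generation(s)%s\n",
    length(x$selected_idx), x$best_rmsecv, x$best_lv, x$generations,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}
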