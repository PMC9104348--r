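test_that("autoscale centres, scales, flags constants, and is reapplicable", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- autoscale(X)
  expect_equal(sc$X[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(sc$X[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(sc$zero_variance["b"])
  # reapplying the stored transform reproduces the scaled matrix
  sc2 <- autoscale(X, means = sc$means,
                   scales = ifelse(sc$zero_variance, 1, sc$scales))
  sc2$X[, sc$zero_variance] <- 0
  expect_equal(sc2$X, sc$X)
  expect_error(autoscale(X[1, , drop = FALSE]), ">= 2 rows")
})

test_that("glog reduces to log2 at lambda 0 and is monotone", {
  expect_equal(glog(4, lambda = 0), 2)
  expect_equal(glog(0, lambda = 4), log2((0 + 2) / 2))
  expect_equal(glog(0, lambda = 4), 0)
  expect_error(glog(-1), "non-negative")
  set.seed(2)
  for (lam in c(0.01, 1, 100)) {
    x <- sort(runif(50, 0, 50))
    expect_true(all(diff(glog(x, lambda = lam)) > 0))
  }
  # default lambda is the squared minimum positive value
  x <- c(0, 0.5, 2, 8)
  expect_equal(glog(x), glog(x, lambda = 0.25))
})

test_that("pca agrees with a covariance eigendecomposition oracle", {
  set.seed(14)
  X <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
  got <- pca(X, n_components = 6)
  ev <- eigen(cov(X))
  expect_equal(abs(got$loadings), abs(ev$vectors), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(got$explained, ev$values / sum(ev$values), tolerance = 1e-8)
  # full-rank scores reconstruct the matrix
  expect_equal(got$scores %*% t(got$loadings), X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # two perfectly correlated columns: PC1 explains everything
  Y <- scale(cbind(1:5, 2 * (1:5)), scale = FALSE)
  expect_equal(pca(Y, 1)$explained[1], 1)
  expect_warning(pca(Y, 2), "rank")
})

test_that("oPLS-DA with zero orthogonal components equals 1-LV PLS-DA", {
  set.seed(21)
  n <- 24; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("TKO", "CTRL"), each = n / 2)
  X[y == "TKO", 1:2] <- X[y == "TKO", 1:2] + 1
  m0 <- opls_da_fit(X, y, n_orth = 0)
  yy <- ifelse(y == "TKO", 1, -1)
  sc <- autoscale(X)
  fit <- metatrack:::pls1_fit(sc$X, yy - mean(yy), 1)
  ref <- metatrack:::pls1_predict_all(fit, sc$X)[, 1] + mean(yy)
  expect_lt(max(abs(opls_da_predict(m0, X)$y_hat - ref)), 1e-10)
})

test_that("orthogonal filtering removes y-orthogonal structured variation", {
  set.seed(33)
  n <- 40; p <- 20
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * p, sd = 0.1), n, p)
  X[, 1] <- X[, 1] + y  # predictive direction
  base <- opls_da_fit(X, y, n_orth = 1, scale = FALSE)
  # add a strong structured component orthogonal to y
  conf <- rnorm(n)
  conf <- conf - mean(conf) - y * sum(conf * y) / sum(y * y)
  load <- c(rep(0, 5), rep(2, 15))
  X2 <- X + outer(conf, load)
  filt <- opls_da_fit(X2, y, n_orth = 1, scale = FALSE)
  expect_gt(cor(base$t_pred, filt$t_pred), 0.99)
  # predictive scores orthogonal to every orthogonal score
  expect_lt(abs(sum(filt$t_pred * filt$t_orth[, 1])) /
              sqrt(sum(filt$t_pred^2) * sum(filt$t_orth[, 1]^2)), 1e-8)
})

test_that("oPLS-DA separates separable classes and predicts consistently", {
  set.seed(4)
  n <- 30
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("TKO", "CTRL"), each = n / 2)
  X[y == "TKO", 1:3] <- X[y == "TKO", 1:3] + 4
  m <- opls_da_fit(X, y, n_orth = 1)
  pr <- opls_da_predict(m, X)
  expect_equal(pr$class, ifelse(y == "TKO", 1, -1))
  # class coding swap flips predictions
  m_sw <- opls_da_fit(X, ifelse(y == "TKO", "CTRL", "TKO"), n_orth = 1)
  expect_equal(opls_da_predict(m_sw, X)$class, -pr$class)
  expect_error(opls_da_fit(X, rep("TKO", n)), "both classes")
  expect_error(opls_da_predict(m, X[, 1:5]), "feature mismatch")
})

test_that("venetian-blind folds are deterministic and interleaved", {
  f <- metatrack:::venetian_folds(10, 3)
  expect_equal(f, c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1))
})

test_that("venetian-blind CV is perfect on separable data, ~0.5 on null", {
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c("TKO", "CTRL"), n / 2)  # alternating for balanced folds
  X[y == "TKO", 1] <- X[y == "TKO", 1] + 6
  cv <- venetian_blind_cv(X, y, n_orth = 1, n_folds = 10)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$accuracy, 1)
  expect_true(cv$rmsecv >= 0)
  # null labels: accuracy near chance over a few seeds
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(100 * 10), 100, 10)
    yn <- rep(c("TKO", "CTRL"), 50)
    venetian_blind_cv(Xn, yn, n_orth = 1, n_folds = 10)$accuracy
  }, numeric(1))
  expect_true(all(abs(accs - 0.5) <= 0.2))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("leave-one-out via n_folds = n matches a direct LOO oracle", {
  set.seed(77)
  n <- 12
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c("TKO", "CTRL"), n / 2)
  X[y == "TKO", 1] <- X[y == "TKO", 1] + 1.5
  cv <- venetian_blind_cv(X, y, n_orth = 1, n_folds = n)
  oracle <- vapply(seq_len(n), function(i) {
    m <- opls_da_fit(X[-i, ], y[-i], n_orth = 1)
    opls_da_predict(m, X[i, , drop = FALSE])$y_hat
  }, numeric(1))
  expect_equal(cv$y_hat, oracle, tolerance = 1e-12)
})

test_that("single-class training split raises a clear error", {
  X <- matrix(rnorm(12), 6, 2)
  # alternating labels with 2 interleaved folds: each training split is
  # single-class by construction
  y <- c("TKO", "CTRL", "TKO", "CTRL", "TKO", "CTRL")
  expect_error(venetian_blind_cv(X, y, n_folds = 2), "single class")
})

test_that("B/W statistic is invariant to rotation/scaling of scores", {
  set.seed(5)
  s <- rnorm(30)
  y <- rep(c("TKO", "CTRL"), 15)
  b <- metatrack:::bw_statistic(s, y)
  expect_equal(metatrack:::bw_statistic(5 * s + 3, y), b, tolerance = 1e-12)
  expect_equal(metatrack:::bw_statistic(-s, y), b, tolerance = 1e-12)
})

test_that("permutation test reaches the 1/(n+1) floor on separated classes", {
  set.seed(10)
  n <- 24
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c("TKO", "CTRL"), n / 2)
  X[y == "TKO", 1:2] <- X[y == "TKO", 1:2] + 5
  pt <- permutation_test(X, y, n_orth = 1, n_perm = 199, seed = 3)
  expect_equal(pt$p, 1 / 200)
  expect_length(pt$permuted, 199)
  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")
  # deterministic given the seed
  pt2 <- permutation_test(X, y, n_orth = 1, n_perm = 199, seed = 3)
  expect_equal(pt$permuted, pt2$permuted)
})
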