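# The six estimation schemes and the regularization-path generators.

test_that("covariance assembly matches a brute-force summation oracle", {
  set.seed(4)
  X <- matrix(rnorm(50 * 6), 50, 6)
  Y <- matrix(rnorm(50 * 2), 50, 2)
  cv <- assemble_covariances(
    build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L)),
    time_series(Y, fs = 1))
  cxx_oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) cxx_oracle[i, j] <- sum(X[, i] * X[, j])
  cxy_oracle <- matrix(0, 6, 2)
  for (i in 1:6) for (j in 1:2) cxy_oracle[i, j] <- sum(X[, i] * Y[, j])
  expect_equal(cv$cxx, cxx_oracle, ignore_attr = TRUE)
  expect_equal(cv$cxy, cxy_oracle, ignore_attr = TRUE)
  expect_identical(cv$n_samples, 50L)
  # orthonormal X gives the identity autocovariance
  Q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  cq <- assemble_covariances(
    build_lagged_design(time_series(Q, fs = 1), lag_spec(0L, 0L)),
    time_series(rnorm(100), fs = 1))
  expect_equal(cq$cxx, diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  # row mismatch is a shape error
  expect_error(assemble_covariances(
    build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L)),
    time_series(rnorm(20), fs = 1)), "row counts")
})

test_that("OLS recovers planted weights and rejects singular systems", {
  sys <- planted_system(n = 20, p = 3, seed = 2)
  expect_equal(solve_ols(sys$cov), sys$W, tolerance = 1e-8)
  # cxx = I passes cxy straight through
  cv <- trfdecode:::new_cov(diag(3), c(1, 0, 2))
  expect_equal(drop(solve_ols(cv)), c(1, 0, 2))
  # rank-deficient system errors with a condition estimate
  Xr <- cbind(1:10, 2 * (1:10), rnorm(10))
  cvr <- assemble_covariances(
    build_lagged_design(time_series(Xr, fs = 1), lag_spec(0L, 0L)),
    time_series(rnorm(10), fs = 1))
  expect_error(solve_ols(cvr), "condition|singular")
})

test_that("ridge reduces to OLS at zero and shrinks monotonically", {
  sys <- planted_system(n = 40, p = 5, seed = 3, noise_sd = 0.5)
  expect_equal(solve_ridge(sys$cov, 0), solve_ols(sys$cov), tolerance = 1e-10)
  cv <- trfdecode:::new_cov(diag(4), c(2, -1, 0.5, 3))
  expect_equal(drop(solve_ridge(cv, 1.5)), c(2, -1, 0.5, 3) / 2.5)
  norms <- vapply(10^seq(-2, 12, by = 1),
                  function(l) sqrt(sum(solve_ridge(sys$cov, l)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-6)
  expect_error(solve_ridge(sys$cov, -1), "nonnegative")
})

test_that("LRA keeps the smallest rank covering the spectral fraction", {
  # two-eigenvalue hand computation: s = (3, 1), lambda = 0.75 -> K = 1
  cv <- trfdecode:::new_cov(diag(c(3, 1)), c(1, 1))
  expect_equal(drop(solve_lra(cv, 0.75)), c(1 / 3, 0))
  # lambda = 1 on a full-rank system equals OLS
  sys <- planted_system(n = 40, p = 5, seed = 5)
  expect_equal(solve_lra(sys$cov, 1), solve_ols(sys$cov), tolerance = 1e-8)
  expect_error(solve_lra(sys$cov, 0), "\\(0, 1\\]")
  expect_error(solve_lra(trfdecode:::new_cov(matrix(0, 2, 2), c(0, 0)), 0.5),
               "degenerate")
})

test_that("LRA equals an explicit eigenspace-projection oracle", {
  set.seed(11)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- rnorm(80)
  cv <- assemble_covariances(
    build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L)),
    time_series(y, fs = 1))
  for (lam in c(0.3, 0.6, 0.9, 1)) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    K <- which(cumsum(e$values) / sum(e$values) >= lam - 1e-12)[1]
    U <- e$vectors[, 1:K, drop = FALSE]
    oracle <- U %*% diag(1 / e$values[1:K], K) %*% crossprod(U, crossprod(X, y))
    expect_equal(drop(solve_lra(cv, lam)), drop(oracle), tolerance = 1e-8)
  }
})

test_that("LRA is invariant to eigenvector sign conventions", {
  sys <- planted_system(n = 50, p = 5, seed = 6)
  eig <- trfdecode:::cov_eigen(sys$cov)
  flipped <- eig
  flipped$vectors <- flipped$vectors %*% diag(c(-1, 1, -1, 1, -1))
  expect_equal(solve_lra(sys$cov, 0.8, eig = eig),
               solve_lra(sys$cov, 0.8, eig = flipped), tolerance = 1e-10)
})

test_that("shrinkage interpolates between OLS and cross-correlation", {
  sys <- planted_system(n = 40, p = 5, seed = 7, noise_sd = 0.3)
  expect_equal(solve_shrinkage(sys$cov, 0), solve_ols(sys$cov),
               tolerance = 1e-10)
  nu <- sum(diag(sys$cov$cxx)) / 5
  expect_equal(solve_shrinkage(sys$cov, 1), sys$cov$cxy / nu)
  # diagonal hand computation under Eq-style algebra:
  # cxx = diag(2, 0), nu = 1, lambda = 0.5 -> diag(1.5, 0.5)
  cv <- trfdecode:::new_cov(diag(c(2, 0)), c(1, 1))
  expect_equal(drop(solve_shrinkage(cv, 0.5)), c(1 / 1.5, 2))
  expect_error(solve_shrinkage(sys$cov, 1.2), "\\[0, 1\\]")
  # in the eigenbasis every component moves monotonically toward its
  # lambda = 1 value (the denominator is linear in lambda)
  eig <- trfdecode:::cov_eigen(sys$cov)
  comp <- sapply(seq(0, 1, by = 0.1), function(l) {
    drop(crossprod(eig$vectors, solve_shrinkage(sys$cov, l)))
  })
  expect_true(all(apply(comp, 1, function(v) {
    all(diff(v) >= -1e-10) || all(diff(v) <= 1e-10)
  })))
})

test_that("second-difference matrix realizes the derivative penalty", {
  expect_equal(second_difference_matrix(3),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  M <- second_difference_matrix(12)
  expect_equal(rowSums(M), rep(0, 12))            # constants unpenalized
  expect_equal(drop(crossprod(c(1, 2, 3), second_difference_matrix(3) %*%
                                c(1, 2, 3))), 2)  # (1-2)^2 + (2-3)^2
  # penalty identity for random vectors
  set.seed(8)
  for (i in 1:5) {
    w <- rnorm(12)
    expect_equal(drop(crossprod(w, M %*% w)), sum(diff(w)^2),
                 tolerance = 1e-12)
  }
  expect_error(second_difference_matrix(1), ">= 2")
})

test_that("tikhonov reduces to OLS at zero and flattens at large lambda", {
  sys <- planted_system(n = 60, p = 6, seed = 9, noise_sd = 0.2)
  expect_equal(solve_tikhonov(sys$cov, 0), solve_ols(sys$cov),
               tolerance = 1e-8)
  # single-channel design: huge lambda drives W into M's null space
  # (constant across lags)
  x <- rnorm(500)
  d <- build_lagged_design(time_series(x, fs = 1), lag_spec(0L, 7L))
  cv <- assemble_covariances(d, time_series(rnorm(500), fs = 1))
  W <- drop(solve_tikhonov(cv, 1e10))
  expect_lt(max(W) - min(W), 1e-6 * max(abs(W), 1e-30) + 1e-10)
})

test_that("tikhonov matches a generic quadratic-programming oracle", {
  set.seed(10)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- rnorm(80)
  cv <- assemble_covariances(
    build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L)),
    time_series(y, fs = 1))
  M <- second_difference_matrix(6)
  for (lam in c(0.5, 5, 50)) {
    oracle <- quadratic_oracle(X, y, penalty_hessian = M, lambda = lam)
    expect_equal(drop(solve_tikhonov(cv, lam)), oracle, tolerance = 1e-6)
  }
  # block-diagonal option confines smoothing within channels
  x2 <- matrix(rnorm(400), 200, 2)
  d2 <- build_lagged_design(time_series(x2, fs = 1), lag_spec(0L, 2L))
  cv2 <- assemble_covariances(d2, time_series(rnorm(200), fs = 1))
  Wg <- solve_tikhonov(cv2, 10)
  Wb <- solve_tikhonov(cv2, 10, n_channels = 2L, per_channel_blocks = TRUE)
  expect_false(isTRUE(all.equal(Wg, Wb)))
})

test_that("elastic net reproduces closed forms and glmnet", {
  sys <- planted_system(n = 80, p = 5, seed = 12, noise_sd = 0.1)
  # lambda = 0 equals OLS on a standardized well-conditioned system
  Xs <- scale(sys$X); ys <- drop(scale(sys$Y))
  cvs <- assemble_covariances(
    build_lagged_design(time_series(Xs, fs = 1), lag_spec(0L, 0L)),
    time_series(ys, fs = 1))
  fit0 <- solve_elastic_net(Xs, ys, lambda = 0, tol = 1e-8,
                            standardize = FALSE)
  expect_true(fit0$converged)
  expect_lt(max(abs(fit0$W - solve_ols(cvs))), 1e-4)
  # the lasso null threshold zeroes every coefficient exactly
  lmax <- lasso_lambda_max(sys$design, sys$target)
  fitz <- solve_elastic_net(sys$design, sys$target, lambda = lmax * 1.0001,
                            alpha = 1)
  expect_true(all(fitz$W == 0))
  fitnz <- solve_elastic_net(sys$design, sys$target, lambda = lmax * 0.5,
                             alpha = 1)
  expect_true(any(fitnz$W != 0))
  # orthonormal design: per-coefficient soft threshold of the OLS solution
  set.seed(13)
  n <- 100
  # orthonormal, zero-mean columns scaled to unit population variance
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5] * sqrt(n)
  y <- drop(Q %*% c(1.5, -0.4, 0.05, 0) + 0.05 * rnorm(n))
  y <- y - mean(y)
  fit <- solve_elastic_net(Q, y, lambda = 0.2, alpha = 1,
                           standardize = FALSE, tol = 1e-10)
  ols <- drop(crossprod(Q, y)) / colSums(Q^2)
  shrunk <- sign(ols) * pmax(abs(ols) - 0.2 / colMeans(Q^2), 0)
  expect_equal(drop(fit$W), shrunk, tolerance = 1e-6)
  # independent cross-check against glmnet at matched objective (glmnet
  # standardizes the response internally, so hand it a unit-variance y)
  y0 <- drop(sys$Y)
  y0 <- (y0 - mean(y0)) / sqrt(mean((y0 - mean(y0))^2))
  g <- glmnet::glmnet(sys$X, y0, alpha = 0.5, lambda = 0.1,
                      standardize = TRUE, intercept = FALSE,
                      thresh = 1e-12)
  ours <- solve_elastic_net(sys$X, y0, lambda = 0.1, alpha = 0.5, tol = 1e-9)
  expect_lt(max(abs(drop(ours$W) - as.numeric(g$beta))), 5e-3)
})

test_that("elastic net with small alpha approaches ridge at matched penalty", {
  set.seed(14)
  n <- 200; p <- 4
  X <- scale(matrix(rnorm(n * p), n, p))
  X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")       # unit population variance
  y <- drop(X %*% c(1, -0.5, 0.25, 0) + 0.1 * rnorm(n)); y <- y - mean(y)
  alpha <- 0.01; lam <- 0.05
  en <- solve_elastic_net(X, y, lambda = lam, alpha = alpha,
                          standardize = FALSE, tol = 1e-10)
  cvx <- assemble_covariances(
    build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L)),
    time_series(y, fs = 1))
  ridge <- solve_ridge(cvx, n * lam * (1 - alpha))
  expect_lt(max(abs(drop(en$W) - drop(ridge))), 1e-3)
})

test_that("geometric path reproduces the printed ladder", {
  p <- sweep_geometric_lambdas()
  expect_length(p$lambdas, 54)
  expect_equal(p$lambdas[1], 1e-6)
  expect_equal(p$lambdas[2], 1.848e-6)
  expect_equal(p$lambdas[54], 1e-6 * 1.848^53)     # ~1.37e8
  expect_true(all(diff(p$lambdas) > 0))
  ratios <- p$lambdas[-1] / p$lambdas[-54]
  expect_equal(ratios, rep(1.848, 53), tolerance = 1e-12)
  expect_error(sweep_geometric_lambdas(ratio = -1), "positive")
})

test_that("log-sigmoid path stays in (0,1) with additive logit steps", {
  p <- sweep_logsigmoid_lambdas()
  expect_length(p$lambdas, 41)
  expect_equal(p$lambdas[1], 1e-6)
  lgt <- function(x) log(x) - log1p(-x)
  expect_equal(p$lambdas[2], plogis(lgt(1e-6) + 0.475), tolerance = 1e-12)
  expect_equal(p$lambdas[2], 1.608e-6, tolerance = 1e-3)
  expect_equal(p$lambdas[41], plogis(lgt(1e-6) + 40 * 0.475),
               tolerance = 1e-12)
  expect_gt(p$lambdas[41], 0.99)
  expect_true(all(p$lambdas > 0 & p$lambdas < 1))
  expect_true(all(diff(p$lambdas) > 0))
  expect_error(sweep_logsigmoid_lambdas(lambda0 = 2), "inside")
})

test_that("estimator dispatch routes names to the matching solver", {
  sys <- planted_system(n = 50, p = 4, seed = 15, noise_sd = 0.2)
  expect_equal(fit_estimator("ols", sys$cov), solve_ols(sys$cov))
  expect_equal(fit_estimator("ridge", sys$cov, lambda = 2),
               solve_ridge(sys$cov, 2))
  expect_equal(fit_estimator("shrinkage", sys$cov, lambda = 0.4),
               solve_shrinkage(sys$cov, 0.4))
  expect_equal(fit_estimator("elasticnet", lambda = 0.05, alpha = 1,
                             design = sys$design, target = sys$target),
               solve_elastic_net(sys$design, sys$target, 0.05, 1)$W)
  expect_error(fit_estimator("elasticnet", sys$cov, lambda = 1), "raw")
})
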