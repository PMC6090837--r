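# Shared fixtures, built in code.  Small scenarios keep the default test run
# fast; the acceptance tests build the full-scale scenario themselves.

# A small but decodable two-talker dataset (cached per options-combination
# within one test run).
.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function(n_trials = 20L, duration_s = 20, n_channels = 16L,
                          snr_db = -10, seed = 7L, ...) {
  key <- paste(n_trials, duration_s, n_channels, snr_db, seed, ..., sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    sc <- synthetic_scenario(n_trials = n_trials, duration_s = duration_s,
                             n_channels = n_channels, snr_db = snr_db,
                             seed = seed, ...)
    .fixture_cache[[key]] <- generate_dataset(sc)
  }
  .fixture_cache[[key]]
}

# Random regression system with a planted weight matrix.
planted_system <- function(n = 60L, p = 6L, m = 1L, seed = 1L,
                           noise_sd = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  W <- matrix(rnorm(p * m), p, m)
  Y <- X %*% W + noise_sd * matrix(rnorm(n * m), n, m)
  d <- build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L))
  list(X = X, Y = Y, W = W, design = d,
       target = time_series(Y, fs = 1),
       cov = assemble_covariances(d, time_series(Y, fs = 1)))
}

# Generic quadratic-minimization oracle: minimizes the exact penalized
# least-squares objective by BFGS with analytic gradients, independent of
# the closed-form solution path it checks.
quadratic_oracle <- function(X, y, penalty_hessian = NULL, lambda = 0) {
  p <- ncol(X)
  P <- penalty_hessian %||% matrix(0, p, p)
  obj <- function(w) {
    r <- y - X %*% w
    sum(r^2) + lambda * drop(crossprod(w, P %*% w))
  }
  grad <- function(w) {
    drop(-2 * crossprod(X, y - X %*% w) + 2 * lambda * (P %*% w))
  }
  fit <- optim(rep(0, p), obj, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  fit$par
}

# Model wrapping the ground-truth kernel of a dataset (forward direction).
true_forward_model <- function(dataset) {
  k <- dataset$kernel
  W <- array(outer(k$profile, k$topography), dim = c(length(k$profile), 1L,
                                                     length(k$topography)))
  linear_model(W, "forward", k$lag_spec, fs = k$fs)
}
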