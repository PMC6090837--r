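# The six model-estimation schemes.  All but the Elastic Net are closed
# forms over covariance statistics; the spectral ones (OLS/Ridge/LRA/
# Shrinkage) accept a precomputed eigendecomposition of cxx so an entire
# regularization path costs one decomposition.

#' Ordinary least squares solution
#'
#' Solves `W = (X'X)^{-1} X'Y` from covariance statistics via a symmetric
#' (Cholesky) factorization.  Refuses ill-conditioned systems: if the
#' reciprocal condition estimate of `cxx` falls below `1/cond_limit` a
#' singularity error naming the condition estimate is raised.
#'
#' @param cov A `trf_cov`.
#' @param cond_limit Maximum tolerated condition number (default `1e12`).
#' @param eig Optional precomputed `cov_eigen()` decomposition.
#' @return Weight matrix `W` (columns = outputs).
#' @export
solve_ols <- function(cov, cond_limit = 1e12, eig = NULL) {
  if (!inherits(cov, "trf_cov")) stop_invalid("`cov` must be a trf_cov")
  if (!is.null(eig)) {
    s <- eig$values
    if (min(s) <= 0 || max(s) / min(s) > cond_limit) {
      stop_invalid(sprintf(
        "singular or ill-conditioned autocovariance (condition estimate %.3g)",
        if (min(s) <= 0) Inf else max(s) / min(s)))
    }
    return(eig$vectors %*% ((1 / s) * crossprod(eig$vectors, cov$cxy)))
  }
  rc <- tryCatch(rcond(cov$cxx), error = function(e) 0)
  if (!is.finite(rc) || rc < 1 / cond_limit) {
    stop_invalid(sprintf(
      "singular or ill-conditioned autocovariance (condition estimate %.3g)",
      1 / max(rc, .Machine$double.xmin)))
  }
  ch <- tryCatch(chol(cov$cxx), error = function(e) {
    stop_invalid("singular autocovariance: Cholesky factorization failed")
  })
  backsolve(ch, forwardsolve(t(ch), cov$cxy))
}

#' Ridge (L2) regularized solution
#'
#' `W = (X'X + lambda I)^{-1} X'Y`.  `lambda = 0` reduces to OLS.
#'
#' @param cov A `trf_cov`.
#' @param lambda Nonnegative penalty weight.
#' @param eig Optional precomputed `cov_eigen()` decomposition.
#' @return Weight matrix.
#' @export
solve_ridge <- function(cov, lambda, eig = NULL) {
  if (!inherits(cov, "trf_cov")) stop_invalid("`cov` must be a trf_cov")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_invalid("`lambda` must be a single nonnegative number")
  }
  if (!is.null(eig)) {
    d <- eig$values + lambda
    if (any(d <= 0)) stop_invalid("singular regularized system at lambda = ", lambda)
    return(eig$vectors %*% ((1 / d) * crossprod(eig$vectors, cov$cxy)))
  }
  A <- cov$cxx + diag(lambda, nrow(cov$cxx))
  ch <- tryCatch(chol(A), error = function(e) {
    stop_invalid("singular regularized system at lambda = ", lambda)
  })
  backsolve(ch, forwardsolve(t(ch), cov$cxy))
}

#' Low-rank approximation (LRA) solution
#'
#' Eigendecomposes `X'X = U S U'` and keeps the smallest leading rank `K`
#' whose eigenvalue sum covers a fraction `lambda` of the total, then
#' pseudo-inverts on that subspace:
#' `W = U diag(1/s_1..1/s_K, 0..) U' X'Y`.  `lambda = 1` keeps every
#' nonzero component.  Eigenvalues below `1e-12` of the maximum are treated
#' as zero.
#'
#' @param cov A `trf_cov`.
#' @param lambda Fraction of spectral energy to retain, in (0, 1\].
#' @param eig Optional precomputed `cov_eigen()` decomposition.
#' @return Weight matrix.
#' @export
solve_lra <- function(cov, lambda, eig = NULL) {
  if (!inherits(cov, "trf_cov")) stop_invalid("`cov` must be a trf_cov")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1) {
    stop_invalid("LRA `lambda` must lie in (0, 1]")
  }
  if (is.null(eig)) eig <- cov_eigen(cov)
  s <- eig$values
  tot <- sum(s)
  if (tot <= 0) stop_invalid("degenerate input: autocovariance is all zero")
  frac <- cumsum(s) / tot
  K <- which(frac >= lambda - 1e-12)[1]
  K <- min(K, sum(s > 0))
  sinv <- numeric(length(s))
  sinv[seq_len(K)] <- 1 / s[seq_len(K)]
  eig$vectors %*% (sinv * crossprod(eig$vectors, cov$cxy))
}

#' Shrinkage-regularized solution
#'
#' Flattens the eigenvalue spectrum of the autocovariance toward its average
#' eigenvalue `nu = trace(X'X)/d`:
#' `W = ((1-lambda) X'X + lambda nu I)^{-1} X'Y`.  `lambda = 0` is OLS;
#' `lambda = 1` reduces to a cross-correlation `X'Y / nu`.
#'
#' @param cov A `trf_cov`.
#' @param lambda Shrinkage amount in \[0, 1\].
#' @param eig Optional precomputed `cov_eigen()` decomposition.
#' @return Weight matrix.
#' @export
solve_shrinkage <- function(cov, lambda, eig = NULL) {
  if (!inherits(cov, "trf_cov")) stop_invalid("`cov` must be a trf_cov")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop_invalid("Shrinkage `lambda` must lie in [0, 1]")
  }
  nu <- sum(diag(cov$cxx)) / nrow(cov$cxx)
  if (lambda == 1) return(cov$cxy / nu)
  if (!is.null(eig)) {
    d <- (1 - lambda) * eig$values + lambda * nu
    if (any(d <= 0)) stop_invalid("singular shrunk system at lambda = ", lambda)
    return(eig$vectors %*% ((1 / d) * crossprod(eig$vectors, cov$cxy)))
  }
  A <- (1 - lambda) * cov$cxx + diag(lambda * nu, nrow(cov$cxx))
  ch <- tryCatch(chol(A), error = function(e) {
    stop_invalid("singular shrunk system at lambda = ", lambda)
  })
  backsolve(ch, forwardsolve(t(ch), cov$cxy))
}

#' Second-difference (first-derivative) penalty matrix
#'
#' The tridiagonal matrix `M = D'D` for `D` the first-difference operator:
#' diagonal 1 at both ends and 2 inside, off-diagonals -1.  For any weight
#' vector `w`, `w' M w = sum_i (w_i - w_{i+1})^2`, the first-derivative
#' smoothness penalty.  Row sums are zero, so constant vectors are
#' unpenalized.
#'
#' @param d Dimension (>= 2).
#' @return A `d x d` symmetric matrix.
#' @examples
#' second_difference_matrix(3)
#' @export
second_difference_matrix <- function(d) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 2L) stop_invalid("`d` must be an integer >= 2")
  M <- diag(2, d)
  M[1, 1] <- 1; M[d, d] <- 1
  idx <- seq_len(d - 1L)
  M[cbind(idx, idx + 1L)] <- -1
  M[cbind(idx + 1L, idx)] <- -1
  M
}

#' Tikhonov (temporal smoothness) regularized solution
#'
#' `W = (X'X + lambda M)^{-1} X'Y` with `M` the second-difference penalty at
#' the full combined channel-lag dimension.  With a multichannel regressor
#' (the backward model) the single global `M` lets smoothing leak across the
#' boundary between adjacent channel blocks; set
#' `per_channel_blocks = TRUE` for a block-diagonal `M` that confines the
#' penalty within channels.
#'
#' @param cov A `trf_cov`.
#' @param lambda Nonnegative penalty weight.
#' @param n_channels Number of regressor channels (needed only for
#'   `per_channel_blocks = TRUE`).
#' @param per_channel_blocks Use a block-diagonal penalty (default `FALSE`,
#'   the single global matrix).
#' @return Weight matrix.
#' @export
solve_tikhonov <- function(cov, lambda, n_channels = 1L,
                           per_channel_blocks = FALSE) {
  if (!inherits(cov, "trf_cov")) stop_invalid("`cov` must be a trf_cov")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_invalid("`lambda` must be a single nonnegative number")
  }
  d <- nrow(cov$cxx)
  if (per_channel_blocks) {
    if (d %% n_channels != 0L) stop_invalid("`d` not divisible by `n_channels`")
    L <- d %/% n_channels
    Mb <- second_difference_matrix(L)
    M <- matrix(0, d, d)
    for (c in seq_len(n_channels)) {
      idx <- ((c - 1L) * L + 1L):(c * L)
      M[idx, idx] <- Mb
    }
  } else {
    M <- second_difference_matrix(d)
  }
  A <- cov$cxx + lambda * M
  ch <- tryCatch(chol(A), error = function(e) {
    stop_invalid("singular Tikhonov-regularized system at lambda = ", lambda)
  })
  backsolve(ch, forwardsolve(t(ch), cov$cxy))
}

#' Fit a model estimator by name
#'
#' Uniform entry point over the six estimation schemes.  The five
#' covariance-based solvers take a `trf_cov`; the Elastic Net needs the raw
#' design and target for coordinate descent (pass `design` and `target`).
#'
#' @param estimator One of `"ols"`, `"ridge"`, `"lra"`, `"shrinkage"`,
#'   `"tikhonov"`, `"elasticnet"`.
#' @param cov A `trf_cov` (covariance solvers).
#' @param lambda Regularization parameter (ignored for `"ols"`).
#' @param alpha Elastic Net L1/L2 balance in (0, 1\].
#' @param design,target Raw `trf_design` / `trf_ts` (Elastic Net only).
#' @param eig Optional shared eigendecomposition (spectral solvers).
#' @param ... Passed through to the scheme-specific solver.
#' @return Weight matrix.
#' @export
fit_estimator <- function(estimator, cov = NULL, lambda = 0, alpha = 1,
                          design = NULL, target = NULL, eig = NULL, ...) {
  estimator <- match.arg(estimator,
                         c("ols", "ridge", "lra", "shrinkage", "tikhonov",
                           "elasticnet"))
  if (estimator == "elasticnet") {
    if (is.null(design) || is.null(target)) {
      stop_invalid("Elastic Net needs the raw `design` and `target` ",
                   "(coordinate descent does not run on covariances)")
    }
    fit <- solve_elastic_net(design, target, lambda = lambda, alpha = alpha, ...)
    return(fit$W)
  }
  if (is.null(cov)) stop_invalid("covariance solvers need `cov`")
  switch(estimator,
         ols = solve_ols(cov, eig = eig, ...),
         ridge = solve_ridge(cov, lambda, eig = eig, ...),
         lra = solve_lra(cov, lambda, eig = eig, ...),
         shrinkage = solve_shrinkage(cov, lambda, eig = eig, ...),
         tikhonov = solve_tikhonov(cov, lambda, ...))
}
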