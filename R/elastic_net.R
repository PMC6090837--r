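# Elastic Net by cyclic coordinate descent with soft-thresholding.  The one
# estimator that consumes the raw design rather than covariance statistics:
# the objective
#   (1/2N) ||Y - XW||^2 + lambda [ (1-alpha) ||W||^2 / 2 + alpha ||W||_1 ]
# is minimized per output column.  Columns are standardized internally
# (zero mean, unit variance) and the solution back-transformed.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Elastic Net solution by cyclic coordinate descent
#'
#' Minimizes `(1/2N)||Y - XW||^2 + lambda[(1-alpha)||W||^2/2 + alpha||W||_1]`
#' by cycling soft-threshold updates over coefficients until the largest
#' coefficient change falls below `tol` or `max_iter` sweeps are exhausted.
#' With `alpha = 1` this is the Lasso; `lambda = 0` recovers the
#' unpenalized least-squares solution.
#'
#' @param design A `trf_design` (or plain numeric matrix).
#' @param target A `trf_ts` (or numeric matrix/vector) with matching rows.
#' @param lambda Nonnegative overall penalty strength.
#' @param alpha L1/L2 balance in (0, 1\].
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default `1e-6`).
#' @param max_iter Maximum coordinate-descent sweeps (default 10000).
#' @param standardize Standardize columns internally (default `TRUE`).
#' @param w_init Optional warm-start coefficient matrix (standardized scale)
#'   for path fitting; must not change converged results beyond `tol`.
#' @return List with `W` (weights on the original scale), `converged`
#'   (logical), `n_iter`, and `W_std` (standardized-scale weights, for warm
#'   starts).  Non-convergence raises a warning, never silent success.
#' @export
solve_elastic_net <- function(design, target, lambda, alpha = 1,
                              tol = 1e-6, max_iter = 10000L,
                              standardize = TRUE, w_init = NULL) {
  X <- if (inherits(design, "trf_design")) design$values else as.matrix(design)
  Y <- if (is_time_series(target)) target$samples else as.matrix(target)
  if (nrow(X) != nrow(Y)) stop_invalid("design and target row counts differ")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_invalid("`lambda` must be a single nonnegative number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop_invalid("`alpha` must lie in (0, 1]")
  }
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (standardize) {
    mx <- colMeans(X)
    sx <- sqrt(colMeans(X^2) - mx^2)      # population sd, glmnet convention
    sx[sx == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mx), 2L, sx, "/")
    my <- colMeans(Y)
    Ys <- sweep(Y, 2L, my)
  } else {
    Xs <- X; Ys <- Y
    sx <- rep(1, p)
  }
  colnorm <- colMeans(Xs^2)               # = 1 when standardized
  W <- matrix(0, p, m)
  if (!is.null(w_init)) W[] <- w_init
  converged <- TRUE
  iters <- integer(m)
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)
  for (k in seq_len(m)) {
    w <- W[, k]
    y <- Ys[, k]
    resid <- y - Xs %*% w
    it <- 0L
    repeat {
      it <- it + 1L
      delta_max <- 0
      for (j in seq_len(p)) {
        wj <- w[j]
        rho <- sum(Xs[, j] * resid) / n + colnorm[j] * wj
        wj_new <- soft_threshold(rho, l1) / (colnorm[j] + l2)
        if (wj_new != wj) {
          resid <- resid - Xs[, j] * (wj_new - wj)
          delta_max <- max(delta_max, abs(wj_new - wj))
          w[j] <- wj_new
        }
      }
      if (delta_max < tol || it >= max_iter) break
    }
    if (it >= max_iter && delta_max >= tol) {
      converged <- FALSE
      warning("Elastic Net coordinate descent did not converge within ",
              max_iter, " sweeps (output ", k, ")", call. = FALSE)
    }
    iters[k] <- it
    W[, k] <- w
  }
  W_orig <- W / sx
  list(W = W_orig, W_std = W, converged = converged, n_iter = iters)
}

#' Smallest penalty that nulls every Lasso coefficient
#'
#' For `alpha = 1` and standardized columns, coordinate descent yields the
#' all-zero solution exactly when `lambda >= max |x_j' y| / N`.
#'
#' @inheritParams solve_elastic_net
#' @return The null-threshold penalty value.
#' @export
lasso_lambda_max <- function(design, target, standardize = TRUE) {
  X <- if (inherits(design, "trf_design")) design$values else as.matrix(design)
  Y <- if (is_time_series(target)) target$samples else as.matrix(target)
  n <- nrow(X)
  if (standardize) {
    mx <- colMeans(X)
    sx <- sqrt(colMeans(X^2) - mx^2); sx[sx == 0] <- 1
    X <- sweep(sweep(X, 2L, mx), 2L, sx, "/")
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  max(abs(crossprod(X, Y))) / n
}
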