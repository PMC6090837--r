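# Regularization-path generators.  Estimators whose penalty is unbounded
# (Ridge, Tikhonov, Lasso) sweep a geometric path from 1e-6 to ~1.4e8;
# estimators whose parameter lives in (0, 1) (LRA, Shrinkage, Elastic Net)
# sweep a log-sigmoid path that compresses the same logarithmic ladder into
# the unit interval.  The two scales are NOT comparable across schemes.

new_path <- function(lambdas, family) {
  structure(list(lambdas = lambdas, family = family), class = "trf_path")
}

#' @export
print.trf_path <- function(x, ...) {
  cat(sprintf("<trf_path> %s, %d values in [%.3g, %.3g]\n",
              x$family, length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Geometric regularization path
#'
#' `lambda_n = lambda0 * ratio^n` for `n = 0..n_steps-1`.  The defaults give
#' the standard 54-step ladder from `1e-6` to about `1.37e8`.
#'
#' @param lambda0 First (positive) value.
#' @param ratio Common ratio (> 0; > 1 for an increasing path).
#' @param n_steps Number of values (>= 1).
#' @return A `trf_path` with family `"geometric"`.
#' @examples
#' p <- sweep_geometric_lambdas()
#' length(p$lambdas)  # 54
#' @export
sweep_geometric_lambdas <- function(lambda0 = 1e-6, ratio = 1.848,
                                    n_steps = 54L) {
  if (!is.numeric(lambda0) || lambda0 <= 0) stop_invalid("`lambda0` must be positive")
  if (!is.numeric(ratio) || ratio <= 0) stop_invalid("`ratio` must be positive")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop_invalid("`n_steps` must be >= 1")
  new_path(lambda0 * ratio^(seq_len(n_steps) - 1L), "geometric")
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p) - log1p(-p)

#' Log-sigmoid regularization path
#'
#' Iterates `lambda <- logsig(logit(lambda) + step)` so the path climbs a
#' uniform ladder in logit space while staying inside (0, 1).  The defaults
#' give 41 values from `1e-6` to about 0.994.
#'
#' @param lambda0 First value, strictly inside (0, 1).
#' @param step Additive logit increment per iteration (default 0.475).
#' @param n_steps Total number of values emitted, including `lambda0`.
#' @return A `trf_path` with family `"logsigmoid"`.
#' @export
sweep_logsigmoid_lambdas <- function(lambda0 = 1e-6, step = 0.475,
                                     n_steps = 41L) {
  if (!is.numeric(lambda0) || lambda0 <= 0 || lambda0 >= 1) {
    stop_invalid("`lambda0` must lie strictly inside (0, 1)")
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop_invalid("`n_steps` must be >= 1")
  # logit increments are additive, so the closed form is exact
  new_path(logistic(logit(lambda0) + step * (seq_len(n_steps) - 1L)),
           "logsigmoid")
}

#' Default regularization path for an estimator
#'
#' Ridge, Tikhonov and the Lasso (`alpha = 1`) take the unbounded geometric
#' path; LRA, Shrinkage and Elastic Net with `alpha < 1` take the
#' log-sigmoid path on (0, 1); OLS has no hyperparameter (a single 0).
#'
#' @param estimator Estimator name.
#' @param alpha Elastic Net balance (only consulted for `"elasticnet"`).
#' @return A `trf_path`.
#' @export
default_lambda_path <- function(estimator, alpha = 1) {
  estimator <- match.arg(estimator,
                         c("ols", "ridge", "lra", "shrinkage", "tikhonov",
                           "elasticnet"))
  switch(estimator,
         ols = new_path(0, "geometric"),
         ridge = ,
         tikhonov = sweep_geometric_lambdas(),
         lra = ,
         shrinkage = sweep_logsigmoid_lambdas(),
         elasticnet = if (alpha >= 1) sweep_geometric_lambdas()
                      else sweep_logsigmoid_lambdas())
}
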