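# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library calls never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilizing transform `atanh(r)` applied to correlations before
#' averaging or inferential comparison; `fisher_z_inv()` maps back.
#'
#' @param r Correlation(s) in (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Arcsine transform of a proportion
#'
#' `asin(sqrt(p))`, the variance-stabilizing transform used for accuracies
#' (range 0--1) before averaging; `arcsine_inv()` maps back.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s).
#' @export
arcsine <- function(p) asin(sqrt(p))

#' @rdname arcsine
#' @param a Arcsine-transformed value(s).
#' @export
arcsine_inv <- function(a) sin(a)^2

# Mean of correlations through Fisher z; tolerant of r == 1 by clamping.
fisher_mean <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

stop_invalid <- function(...) stop(..., call. = FALSE)
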