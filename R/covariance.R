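# Covariance sufficient statistics.  All closed-form estimators consume
# (X'X, X'Y); column sums and target sums are carried along so that Pearson
# correlations of predictions X W against targets can be computed exactly
# from the statistics alone, without rebuilding the design matrix.  This is
# what makes cross-validation at the full study scale (192k samples x 2178
# columns) tractable: per-trial statistics are accumulated and summed, so
# lagged samples never leak across trial boundaries.

#' Assemble covariance statistics from a design and a target
#'
#' Computes the autocovariance `cxx = X'X` and cross-covariance `cxy = X'Y`
#' exactly, together with `X` column sums, `Y` sums, `Y` sums of squares and
#' the sample count (used downstream to score correlations without the raw
#' data).
#'
#' @param design A `trf_design`.
#' @param target A `trf_ts` with the same number of rows.
#' @return A `trf_cov` with fields `cxx`, `cxy`, `xsum`, `ysum`, `yss`,
#'   `n_samples`.
#' @export
assemble_covariances <- function(design, target) {
  if (!inherits(design, "trf_design")) stop_invalid("`design` must be a trf_design")
  assert_ts(target, "target")
  X <- design$values; Y <- target$samples
  if (nrow(X) != nrow(Y)) {
    stop_invalid("design (", nrow(X), " rows) and target (", nrow(Y),
                 " rows) must have equal row counts")
  }
  structure(list(cxx = unname(crossprod(X)), cxy = unname(crossprod(X, Y)),
                 xsum = unname(colSums(X)), ysum = unname(colSums(Y)),
                 yss = unname(colSums(Y^2)), n_samples = nrow(X)),
            class = "trf_cov")
}

new_cov <- function(cxx, cxy, xsum = NULL, ysum = NULL, yss = NULL,
                    n_samples = NA_integer_) {
  cxy <- as.matrix(cxy)
  structure(list(cxx = cxx, cxy = cxy,
                 xsum = xsum %||% rep(0, nrow(cxx)),
                 ysum = ysum %||% rep(0, ncol(cxy)),
                 yss = yss %||% rep(0, ncol(cxy)),
                 n_samples = n_samples),
            class = "trf_cov")
}

#' Sum covariance statistics
#'
#' Adds `trf_cov` objects elementwise, e.g. to pool per-trial or per-fold
#' statistics into a training set.
#'
#' @param covs List of `trf_cov` objects with identical dimensions.
#' @return A pooled `trf_cov`.
#' @export
combine_covariances <- function(covs) {
  if (inherits(covs, "trf_cov")) return(covs)
  stopifnot(length(covs) >= 1L)
  out <- covs[[1]]
  for (s in covs[-1]) {
    out$cxx <- out$cxx + s$cxx
    out$cxy <- out$cxy + s$cxy
    out$xsum <- out$xsum + s$xsum
    out$ysum <- out$ysum + s$ysum
    out$yss <- out$yss + s$yss
    out$n_samples <- out$n_samples + s$n_samples
  }
  out
}

#' @export
print.trf_cov <- function(x, ...) {
  cat(sprintf("<trf_cov> %d x %d autocovariance, %d target(s), n = %d\n",
              nrow(x$cxx), ncol(x$cxx), ncol(x$cxy), x$n_samples))
  invisible(x)
}

# Eigendecomposition of cxx, shared across an entire lambda path for the
# spectral solvers (ols/ridge/lra/shrinkage).  Tiny negative eigenvalues
# from numerical PSD noise are clamped to zero.
cov_eigen <- function(cov) {
  e <- eigen(cov$cxx, symmetric = TRUE)
  smax <- max(e$values, 0)
  e$values[e$values < 1e-12 * smax] <- 0
  list(values = e$values, vectors = e$vectors)
}

# Pearson r of the prediction X w against each target column, from
# sufficient statistics only:
#   sum(a)  = xsum' w,  sum(a^2) = w' cxx w,  sum(a y) = w' cxy.
cor_from_stats <- function(W, cov) {
  W <- as.matrix(W)
  n <- cov$n_samples
  sa <- drop(crossprod(cov$xsum, W))            # per output: sum of prediction
  saa <- colSums(W * (cov$cxx %*% W))           # sum of squared prediction
  say <- colSums(W * cov$cxy)                   # sum of prediction * target
  var_a <- saa - sa^2 / n
  var_y <- cov$yss - cov$ysum^2 / n
  num <- say - sa * cov$ysum / n
  r <- num / sqrt(pmax(var_a, 0) * pmax(var_y, 0))
  r[!is.finite(r)] <- NA_real_
  r
}
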