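# Lag specification, lag-augmented design matrices, and the linear model
# container.  Sign convention: column (c, f) of the design holds the
# regressor sample t - f, so positive lags mean the regressor PRECEDES the
# target.  A forward (encoding) model therefore uses stimulus lags
# 0..+kernel; a backward (decoding) model uses EEG lags -kernel..0 (the EEG
# follows the envelope it reconstructs).

#' Lag specification
#'
#' Integer lag range (in samples) used to augment a regressor with
#' time-shifted copies of itself.  Positive lag `f` means the regressor
#' sample `t - f` predicts the target at `t` (regressor precedes target).
#'
#' @param min_lag,max_lag Integer lags in samples, `min_lag <= max_lag`.
#' @return A `trf_lagspec` object.
#' @examples
#' lag_spec(0, 32)       # forward kernel: 0.5 s at 64 Hz, 33 lags
#' lag_spec(-32, 0)      # backward kernel: EEG follows the envelope
#' @export
lag_spec <- function(min_lag, max_lag) {
  min_lag <- as.integer(min_lag); max_lag <- as.integer(max_lag)
  if (length(min_lag) != 1L || length(max_lag) != 1L ||
      is.na(min_lag) || is.na(max_lag)) {
    stop_invalid("lags must be single integers")
  }
  if (min_lag > max_lag) stop_invalid("`min_lag` must be <= `max_lag`")
  structure(list(min_lag = min_lag, max_lag = max_lag), class = "trf_lagspec")
}

#' @rdname lag_spec
#' @param spec A `trf_lagspec`.
#' @export
n_lags <- function(spec) spec$max_lag - spec$min_lag + 1L

#' @rdname lag_spec
#' @export
lags <- function(spec) seq.int(spec$min_lag, spec$max_lag)

#' Default causal kernel lag window
#'
#' The standard 0.5 s causal kernel: stimulus lags `0..round(kernel_s*fs)`
#' for a forward model, EEG lags `-round(kernel_s*fs)..0` for a backward
#' model (33 lags at 64 Hz).
#'
#' @param direction `"forward"` or `"backward"`.
#' @param fs Sampling rate in Hz.
#' @param kernel_s Kernel length in seconds (default 0.5).
#' @return A `trf_lagspec`.
#' @export
default_lag_spec <- function(direction = c("forward", "backward"), fs,
                             kernel_s = 0.5) {
  direction <- match.arg(direction)
  k <- as.integer(round(kernel_s * fs))
  if (direction == "forward") lag_spec(0L, k) else lag_spec(-k, 0L)
}

#' Build a time-lag-augmented design matrix
#'
#' Augments each channel of `ts` with shifted copies at every lag of
#' `spec`, zero-padded at the edges so the row count equals the input
#' sample count.  Columns are ordered channel-major with lags ascending
#' within each channel, and `column_map` records the (channel, lag) ->
#' column bijection.
#'
#' @param ts A `trf_ts` regressor (envelope for forward, EEG for backward).
#' @param spec A `trf_lagspec`.
#' @return A `trf_design` with fields `values` (time x channels*lags),
#'   `column_map` (data.frame: channel, lag, column), `lag_spec`,
#'   `n_channels`, `fs`.
#' @examples
#' d <- build_lagged_design(time_series(1:5, fs = 1), lag_spec(0, 2))
#' d$values  # lag-0, lag-1, lag-2 shifted columns
#' @export
build_lagged_design <- function(ts, spec) {
  assert_ts(ts)
  if (!inherits(spec, "trf_lagspec")) stop_invalid("`spec` must be a trf_lagspec")
  n <- n_samples(ts); nc <- n_channels(ts); L <- n_lags(spec)
  if (L > n) {
    stop_invalid("lag count (", L, ") exceeds series length (", n, ")")
  }
  lag_vals <- lags(spec)
  X <- matrix(0, n, nc * L)
  for (c in seq_len(nc)) {
    xc <- ts$samples[, c]
    for (i in seq_len(L)) {
      f <- lag_vals[i]
      col <- (c - 1L) * L + i
      if (f >= 0L) {
        if (f < n) X[(f + 1L):n, col] <- xc[1:(n - f)]
      } else {
        if (-f < n) X[1:(n + f), col] <- xc[(1L - f):n]
      }
    }
  }
  cmap <- data.frame(
    channel = rep(seq_len(nc), each = L),
    lag = rep(lag_vals, nc),
    column = seq_len(nc * L)
  )
  structure(list(values = X, column_map = cmap, lag_spec = spec,
                 n_channels = nc, fs = ts$fs, channel_labels = ts$labels),
            class = "trf_design")
}

#' @export
print.trf_design <- function(x, ...) {
  cat(sprintf("<trf_design> %d samples x %d columns (%d channels x %d lags %d..%d)\n",
              nrow(x$values), ncol(x$values), x$n_channels,
              n_lags(x$lag_spec), x$lag_spec$min_lag, x$lag_spec$max_lag))
  invisible(x)
}

#' Linear stimulus-response model
#'
#' Coefficient container for a forward or backward temporal response
#' function.  `weights` is a lag x input-channel x output-channel array; a
#' forward model has one input channel (the envelope), a backward model one
#' output channel (the reconstructed envelope).  There is no intercept:
#' inputs are z-normalized upstream.
#'
#' @param weights Numeric array `[n_lags, n_inputs, n_outputs]`, or a matrix
#'   `(n_lags*n_inputs) x n_outputs` in channel-major column order.
#' @param direction `"forward"` or `"backward"`.
#' @param spec The `trf_lagspec` the weights are indexed by.
#' @param fs Sampling rate in Hz.
#' @param n_inputs Required when `weights` is a flat matrix.
#' @return A `trf_model`.
#' @export
linear_model <- function(weights, direction = c("forward", "backward"),
                         spec, fs, n_inputs = NULL) {
  direction <- match.arg(direction)
  if (!inherits(spec, "trf_lagspec")) stop_invalid("`spec` must be a trf_lagspec")
  L <- n_lags(spec)
  if (is.matrix(weights)) {
    if (is.null(n_inputs)) stop_invalid("`n_inputs` needed for flat weights")
    if (nrow(weights) != L * n_inputs) {
      stop_invalid("flat weights have ", nrow(weights), " rows; expected ",
                   L * n_inputs)
    }
    weights <- array(weights, dim = c(L, n_inputs, ncol(weights)))
  }
  if (length(dim(weights)) != 3L || dim(weights)[1] != L) {
    stop_invalid("`weights` must be a lag x input x output array matching `spec`")
  }
  if (!all(is.finite(weights))) stop_invalid("model weights must be finite")
  if (direction == "forward" && dim(weights)[2] != 1L) {
    stop_invalid("a forward model has a single input channel (the envelope)")
  }
  if (direction == "backward" && dim(weights)[3] != 1L) {
    stop_invalid("a backward model has a single output channel (the envelope)")
  }
  structure(list(weights = weights, direction = direction, lag_spec = spec,
                 fs = fs), class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %s: %d lags x %d inputs -> %d outputs @ %g Hz\n",
              x$direction, d[1], d[2], d[3], x$fs))
  invisible(x)
}

# Flatten model weights to the (channel-major, lag-inner) column order of
# build_lagged_design.  Array storage order (lag fastest, then channel)
# matches that layout, so this is a plain reshape.
flatten_weights <- function(model) {
  d <- dim(model$weights)
  matrix(model$weights, nrow = d[1] * d[2], ncol = d[3])
}

#' Apply a linear model to a design matrix
#'
#' Computes the prediction `Y-hat = X W`: the predicted EEG (forward) or the
#' reconstructed envelope (backward).
#'
#' @param model A `trf_model`.
#' @param design A `trf_design` built with the model's lag window from the
#'   matching regressor.
#' @return A `trf_ts` with one column per output channel and the same row
#'   count as the design.
#' @export
apply_model <- function(model, design) {
  if (!inherits(model, "trf_model")) stop_invalid("`model` must be a trf_model")
  if (!inherits(design, "trf_design")) stop_invalid("`design` must be a trf_design")
  W <- flatten_weights(model)
  if (ncol(design$values) != nrow(W)) {
    stop_invalid("design has ", ncol(design$values), " columns but the model ",
                 "expects ", nrow(W), " (lags x input channels)")
  }
  if (!identical(lags(design$lag_spec), lags(model$lag_spec))) {
    stop_invalid("design and model lag windows differ")
  }
  time_series(design$values %*% W, fs = design$fs,
              channel_labels = paste0("out", seq_len(ncol(W))))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit validation: equal lengths of
#' at least 2 and nonzero variance in both inputs (a zero-variance input is
#' an error, never a silent 0).
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_invalid("`a` and `b` must have equal length")
  if (length(a) < 2L) stop_invalid("need at least 2 samples to correlate")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop_invalid("inputs must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    stop_invalid("undefined correlation: zero-variance input")
  }
  stats::cor(a, b)
}
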