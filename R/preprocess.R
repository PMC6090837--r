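# EEG conditioning chain: line-noise smoothing -> FFT resampling -> linear
# detrend -> causal Butterworth highpass -> joint-decorrelation EOG removal
# -> zero-phase FIR bandpass -> z-normalization (training stats only).

# Apply a function column-wise, preserving the container.
map_channels <- function(ts, f, fs = NULL) {
  out <- apply(ts$samples, 2L, f)
  time_series(out, fs = fs %||% ts$fs, channel_labels = ts$labels)
}

#' Suppress power-line noise by boxcar smoothing
#'
#' Convolves each channel with a square window of `fs / line_freq` samples,
#' which nulls the line frequency and all of its harmonics.  A non-integer
#' window length is realized by linear interpolation between the two
#' flanking integer-length boxcars.  Edges are handled by replicating the
#' first/last sample, so a DC signal passes unchanged.
#'
#' @param ts A `trf_ts`.
#' @param line_freq Line frequency in Hz (must be < `fs/2`).
#' @return Smoothed `trf_ts`.
#' @export
smooth_line_noise <- function(ts, line_freq = 50) {
  assert_ts(ts)
  if (line_freq >= ts$fs / 2) {
    stop_invalid("`line_freq` must be below the Nyquist frequency fs/2")
  }
  len <- ts$fs / line_freq
  n0 <- floor(len)
  w <- len - n0
  # symmetric fractional-length boxcar: n0 full taps flanked by two w/2
  # taps, so the two integer-length windows stay co-centered (zero phase)
  k <- if (w > 0) c(w / 2, rep(1, n0), w / 2) / (n0 + w) else rep(1 / n0, n0)
  half <- (length(k) - 1L) %/% 2L
  map_channels(ts, function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], length(k) - half - 1L))
    as.numeric(stats::filter(xp, rev(k), sides = 1L))[length(k):(n + length(k) - 1L)]
  })
}

#' Resample by Fourier-spectrum truncation
#'
#' Downsamples by truncating the FFT of each channel to the target bandwidth
#' and inverse-transforming; band-limited content below the target Nyquist
#' is preserved.  Output length is `round(n * target_fs / fs)`.  Upsampling
#' is refused.
#'
#' @param ts A `trf_ts`.
#' @param target_fs Target sampling rate (<= `ts$fs`).
#' @return Resampled `trf_ts` at `target_fs`.
#' @export
fft_resample <- function(ts, target_fs) {
  assert_ts(ts)
  if (target_fs > ts$fs) stop_invalid("no upsampling: `target_fs` must be <= fs")
  n <- n_samples(ts)
  m <- as.integer(round(n * target_fs / ts$fs))
  if (m == n) return(ts)
  X <- stats::mvfft(ts$samples)
  Y <- matrix(0 + 0i, m, ncol(X))
  h <- (m - 1L) %/% 2L                    # highest strictly-positive bin kept
  Y[1L, ] <- X[1L, ]
  if (h >= 1L) {
    k <- seq_len(h)
    Y[k + 1L, ] <- X[k + 1L, ]
    Y[m - k + 1L, ] <- X[n - k + 1L, ]
  }
  if (m %% 2L == 0L) {
    kN <- m %/% 2L
    Y[kN + 1L, ] <- 0.5 * (X[kN + 1L, ] + X[n - kN + 1L, ])
  }
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  time_series(out, fs = target_fs, channel_labels = ts$labels)
}

#' Remove per-channel linear trend
#'
#' Subtracts the least-squares line from each channel, leaving zero mean and
#' zero linear trend.
#'
#' @param ts A `trf_ts` with at least 2 samples.
#' @return Detrended `trf_ts`.
#' @export
detrend_linear <- function(ts) {
  assert_ts(ts)
  n <- n_samples(ts)
  if (n < 2L) stop_invalid("need at least 2 samples to detrend")
  t0 <- seq_len(n) - (n + 1) / 2           # centered time axis
  stt <- sum(t0^2)
  Y <- ts$samples
  mu <- colMeans(Y)
  slope <- drop(crossprod(t0, Y)) / stt
  out <- Y - outer(rep(1, n), mu) - outer(t0, slope)
  time_series(out, fs = ts$fs, channel_labels = ts$labels)
}

#' Causal Butterworth highpass
#'
#' Single forward pass of a Butterworth highpass (default 4th order,
#' 0.1 Hz): causal, not zero-phase.  For the default design at 64 Hz the
#' computed group delay stays below 2 samples at all frequencies of 1 Hz
#' and above.
#'
#' @param ts A `trf_ts`.
#' @param cutoff -3 dB cutoff in Hz (default 0.1, must be < `fs/2`).
#' @param order Filter order (default 4).
#' @return Filtered `trf_ts`.
#' @export
highpass_butter <- function(ts, cutoff = 0.1, order = 4L) {
  assert_ts(ts)
  if (cutoff <= 0 || cutoff >= ts$fs / 2) {
    stop_invalid("`cutoff` must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff / (ts$fs / 2), type = "high")
  if (any(abs(polyroot(rev(bf$a))) >= 1 - 1e-12)) {
    stop_invalid("unstable highpass design: cutoff too close to 0 for this fs")
  }
  map_channels(ts, function(x) as.numeric(signal::filter(bf, x)))
}

#' Group delay of an IIR filter design
#'
#' Numerical group delay `-d(phase)/d(omega)` in samples, from the unwrapped
#' phase of the frequency response on a fine grid.
#'
#' @param filt A `signal` filter object (fields `b`, `a`) such as the value
#'   of [signal::butter()].
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies (Hz) at which to report the delay.
#' @return Data frame with `freq` (Hz) and `delay` (samples).
#' @export
filter_group_delay <- function(filt, fs, freqs) {
  dw <- 2 * pi * 1e-5                     # radians/sample step for the slope
  w <- 2 * pi * freqs / fs
  h1 <- freqz_response(filt, w)
  h2 <- freqz_response(filt, w + dw)
  dp <- Arg(h2) - Arg(h1)
  dp <- dp - 2 * pi * round(dp / (2 * pi))  # local unwrap
  data.frame(freq = freqs, delay = -dp / dw)
}

# Complex frequency response of a rational (b, a) filter at radian
# frequencies w (radians/sample).
freqz_response <- function(filt, w) {
  z <- exp(-1i * w)
  num <- outer(z, seq_along(filt$b) - 1L, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1L, `^`) %*% filt$a
  drop(num / den)
}

# Type I linear-phase FIR bandpass coefficients (even order, odd length).
fir_bandpass_coefs <- function(low, high, fs, order) {
  order <- as.integer(order)
  if (order %% 2L != 0L) {
    stop_invalid("FIR `order` must be even (type I linear-phase symmetry)")
  }
  if (high >= fs / 2) stop_invalid("`high` must be below fs/2")
  wl <- low / (fs / 2); wh <- high / (fs / 2)
  if (low <= 0) {
    signal::fir1(order, wh, type = "low")
  } else {
    signal::fir1(order, c(wl, wh), type = "pass")
  }
}

#' Zero-phase windowed-sinc FIR bandpass
#'
#' Applies a type I linear-phase FIR bandpass (windowed sinc, even order)
#' and advances the output by the filter's group delay (`order/2` samples),
#' leaving zero net delay: a band-interior sinusoid passes with no lag.
#'
#' @param ts A `trf_ts`.
#' @param low,high Band edges in Hz (defaults 1 and 9; `high < fs/2`).
#' @param order Even filter order (default 128).
#' @return Filtered `trf_ts`.
#' @export
bandpass_fir_zerophase <- function(ts, low = 1, high = 9, order = 128L) {
  assert_ts(ts)
  b <- as.numeric(fir_bandpass_coefs(low, high, ts$fs, order))
  half <- as.integer(order) %/% 2L
  n <- n_samples(ts)
  map_channels(ts, function(x) {
    y <- as.numeric(signal::filter(b, 1, c(x, numeric(half))))
    y[(half + 1L):(half + n)]
  })
}

#' Per-channel normalization statistics
#'
#' Mean and standard deviation per channel, computed on training rows only
#' so that applying them never leaks test statistics.
#'
#' @param ts A `trf_ts`.
#' @param rows Optional integer vector restricting the estimation rows
#'   (e.g. training-fold samples); default all rows.
#' @return A `trf_norm` with fields `mean` and `sd`.
#' @export
norm_stats <- function(ts, rows = NULL) {
  assert_ts(ts)
  Y <- if (is.null(rows)) ts$samples else ts$samples[rows, , drop = FALSE]
  m <- colMeans(Y)
  s <- apply(Y, 2L, stats::sd)
  if (any(s <= 0)) {
    stop_invalid("degenerate channel: zero standard deviation in ",
                 paste(ts$labels[s <= 0], collapse = ", "))
  }
  structure(list(mean = m, sd = s, labels = ts$labels), class = "trf_norm")
}

#' Z-normalize a series with externally supplied statistics
#'
#' `(x - mean) / sd` per channel using statistics from [norm_stats()]
#' (typically estimated on training data only).
#'
#' @param ts A `trf_ts`.
#' @param stats A `trf_norm`.
#' @return Normalized `trf_ts`.
#' @export
znormalize <- function(ts, stats) {
  assert_ts(ts)
  if (!inherits(stats, "trf_norm")) stop_invalid("`stats` must come from norm_stats()")
  if (length(stats$mean) != n_channels(ts)) {
    stop_invalid("normalization statistics cover ", length(stats$mean),
                 " channels but the series has ", n_channels(ts))
  }
  out <- sweep(sweep(ts$samples, 2L, stats$mean), 2L, stats$sd, "/")
  time_series(out, fs = ts$fs, channel_labels = ts$labels)
}

#' Remove ocular artifact components by joint decorrelation
#'
#' Detects artifact samples by z-scoring the 1--30 Hz bandpassed bipolar
#' VEOG/HEOG channels and marking samples whose absolute z-score exceeds
#' `z_thresh` on either channel; forms the artifact covariance `R_A` over
#' those samples and the whole-data covariance `R`; whitens by the principal
#' components of `R`; solves the symmetric eigenproblem for `R_A` in the
#' whitened space; and regresses out every component whose eigenvalue
#' exceeds `eig_frac` of the maximum.
#'
#' @param eeg A `trf_ts` of EEG channels.
#' @param veog,heog Numeric vectors (bipolar EOG), same length as the EEG.
#' @param z_thresh Artifact detection threshold on the absolute z-score
#'   (default 4).
#' @param eig_frac Eigenvalue fraction above which components are removed
#'   (default 0.8).
#' @param eog_band EOG bandpass in Hz before z-scoring (default `c(1, 30)`).
#' @return List: `cleaned` (`trf_ts`), `report` with `n_removed`,
#'   `n_artifact_samples`, `artifact_fraction`, the removal `eigenvalues`,
#'   spatial `patterns` (columns, sensor space) and `filters`.  If no sample
#'   crosses the threshold the input is returned unchanged with a warning;
#'   if over half of the samples are flagged a suspicious-input warning is
#'   raised.
#' @export
remove_eog_components <- function(eeg, veog, heog, z_thresh = 4,
                                  eig_frac = 0.8, eog_band = c(1, 30)) {
  assert_ts(eeg, "eeg")
  n <- n_samples(eeg)
  if (length(veog) != n || length(heog) != n) {
    stop_invalid("VEOG/HEOG must have the same length as the EEG")
  }
  eog <- time_series(cbind(veog, heog), fs = eeg$fs,
                     channel_labels = c("veog", "heog"))
  bp_high <- min(eog_band[2], eeg$fs / 2 * 0.98)
  eog_bp <- bandpass_fir_zerophase(eog, low = eog_band[1], high = bp_high,
                                   order = 64L)
  z <- scale(eog_bp$samples)               # whole-recording mean/sd
  artifact <- rowSums(abs(z) > z_thresh) > 0
  report <- list(n_removed = 0L, n_artifact_samples = sum(artifact),
                 artifact_fraction = mean(artifact),
                 eigenvalues = numeric(0), patterns = NULL, filters = NULL)
  if (!any(artifact)) {
    warning("no EOG artifact samples detected; returning data unchanged",
            call. = FALSE)
    return(list(cleaned = eeg, report = report))
  }
  if (mean(artifact) > 0.5) {
    warning(sprintf(
      "suspicious input: %.0f%% of samples flagged as EOG artifact",
      100 * mean(artifact)), call. = FALSE)
  }
  X <- eeg$samples
  R <- crossprod(X) / n
  RA <- crossprod(X[artifact, , drop = FALSE]) / sum(artifact)
  eR <- eigen(R, symmetric = TRUE)
  keep <- eR$values > 1e-9 * max(eR$values)    # whitening rank
  Wh <- eR$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eR$values[keep]), sum(keep))
  C <- crossprod(Wh, RA %*% Wh)
  eA <- eigen((C + t(C)) / 2, symmetric = TRUE)
  sel <- eA$values > eig_frac * max(eA$values)
  filters <- Wh %*% eA$vectors[, sel, drop = FALSE]   # sensor-space filters
  comp <- X %*% filters                                # component time courses
  beta <- solve(crossprod(comp), crossprod(comp, X))
  cleaned <- X - comp %*% beta
  patterns <- R %*% filters                            # forward-model patterns
  report$n_removed <- sum(sel)
  report$eigenvalues <- eA$values
  report$patterns <- patterns
  report$filters <- filters
  list(cleaned = time_series(cleaned, fs = eeg$fs, channel_labels = eeg$labels),
       report = report)
}

#' Full EEG conditioning chain
#'
#' Fixed-order pipeline: line-noise smoothing, FFT resampling to
#' `target_fs`, linear detrend, causal Butterworth highpass, optional
#' joint-decorrelation EOG removal, zero-phase FIR bandpass.
#' Z-normalization is NOT part of this chain; it belongs to
#' cross-validation, where statistics come from training data only.
#'
#' @param eeg Raw EEG `trf_ts`.
#' @param veog,heog Optional bipolar EOG vectors at the RAW sampling rate
#'   (resampled internally alongside the EEG); when omitted, the EOG stage
#'   is skipped.
#' @param config Named list overriding defaults: `line_freq` (50),
#'   `target_fs` (64), `hp_cutoff` (0.1), `hp_order` (4), `eog_z_thresh`
#'   (4), `eog_eig_frac` (0.8), `bp_band` (`c(1, 9)`), `bp_order` (128).
#' @return List with `eeg` (conditioned `trf_ts`) and `eog_report`.
#' @export
preprocess_eeg <- function(eeg, veog = NULL, heog = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    line_freq = 50, target_fs = 64, hp_cutoff = 0.1, hp_order = 4L,
    eog_z_thresh = 4, eog_eig_frac = 0.8, bp_band = c(1, 9),
    bp_order = 128L), config)
  x <- eeg
  # line-noise smoothing only applies while the line frequency is within
  # the recorded bandwidth (already-resampled data has none left)
  if (!is.null(cfg$line_freq) && is.finite(cfg$line_freq) &&
      eeg$fs > 2 * cfg$line_freq) {
    x <- smooth_line_noise(x, cfg$line_freq)
  }
  x <- fft_resample(x, cfg$target_fs)
  x <- detrend_linear(x)
  x <- highpass_butter(x, cfg$hp_cutoff, cfg$hp_order)
  eog_report <- NULL
  if (!is.null(veog) && !is.null(heog)) {
    eog <- time_series(cbind(veog, heog), fs = eeg$fs)
    eog <- fft_resample(eog, cfg$target_fs)
    res <- remove_eog_components(x, eog$samples[, 1], eog$samples[, 2],
                                 z_thresh = cfg$eog_z_thresh,
                                 eig_frac = cfg$eog_eig_frac)
    x <- res$cleaned
    eog_report <- res$report
    # reference to common average once ocular components are out
    x <- time_series(x$samples - rowMeans(x$samples), fs = x$fs,
                     channel_labels = x$labels)
  }
  x <- bandpass_fir_zerophase(x, cfg$bp_band[1], cfg$bp_band[2], cfg$bp_order)
  list(eeg = x, eog_report = eog_report)
}
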