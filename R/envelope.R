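# Audio envelope extraction: gammatone filterbank -> per-band analytic
# magnitude -> power-law compression -> across-band sum -> FFT downsample
# -> zero-phase lowpass.

#' ERB-rate scale and ERB-spaced center frequencies
#'
#' `erb_rate()` maps frequency (Hz) to the equivalent-rectangular-bandwidth
#' rate scale; `erb_space()` returns `n` center frequencies equally spaced
#' on that scale between `f_lo` and `f_hi` (inclusive); `erb_bandwidth()`
#' is the ERB (Hz) at a center frequency.
#'
#' @param f Frequency in Hz.
#' @param f_lo,f_hi Band edges in Hz.
#' @param n Number of center frequencies.
#' @return Numeric vector.
#' @export
erb_space <- function(f_lo, f_hi, n) {
  e <- seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n)
  (10^(e / 21.4) - 1) * 1000 / 4.37
}

#' @rdname erb_space
#' @export
erb_rate <- function(f) 21.4 * log10(1 + 4.37 * f / 1000)

#' @rdname erb_space
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# 4th-order gammatone FIR kernel at center frequency fc, unit gain at fc.
gammatone_kernel <- function(fc, fs, duration = 0.1) {
  t <- seq(0, duration, by = 1 / fs)
  b <- 1.019 * erb_bandwidth(fc)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  gain <- Mod(sum(g * exp(-2i * pi * fc * t)))
  g / gain
}

# Causal FIR filtering via FFT convolution, keeping the first n samples.
fir_filter_fft <- function(x, g) {
  n <- length(x)
  L <- stats::nextn(n + length(g) - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                     stats::fft(c(g, numeric(L - length(g)))), inverse = TRUE)) / L
  y[seq_len(n)]
}

# Analytic-signal magnitude (Hilbert envelope) via the FFT.
analytic_magnitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Gammatone envelope of a speech signal
#'
#' Passes mono audio through an `n_bands`-band 4th-order gammatone
#' filterbank with ERB-spaced center frequencies spanning
#' `[f_lo, f_hi]`, takes the magnitude of the analytic signal in each band,
#' raises it to `exponent` (rectification + compression mimicking the
#' auditory periphery), and sums across bands.  The result is a nonnegative
#' envelope at the audio rate.
#'
#' @param audio A single-channel `trf_ts`; its sampling rate must be at
#'   least `2 * f_hi`.
#' @param n_bands Number of filterbank bands (default 31).
#' @param f_lo,f_hi Filterbank frequency range in Hz (defaults 80 and 8000).
#' @param exponent Compressive power (default 0.3).
#' @return A one-channel `trf_ts` envelope at the audio rate.
#' @export
gammatone_envelope <- function(audio, n_bands = 31L, f_lo = 80, f_hi = 8000,
                               exponent = 0.3) {
  assert_ts(audio, "audio")
  if (n_channels(audio) != 1L) stop_invalid("`audio` must be single-channel")
  if (audio$fs < 2 * f_hi) {
    stop_invalid("audio sampling rate (", audio$fs, " Hz) must be >= 2 * f_hi")
  }
  x <- audio$samples[, 1]
  env <- numeric(length(x))
  for (fc in erb_space(f_lo, f_hi, n_bands)) {
    band <- fir_filter_fft(x, gammatone_kernel(fc, audio$fs))
    env <- env + analytic_magnitude(band)^exponent
  }
  time_series(env, fs = audio$fs, channel_labels = "envelope")
}

#' Zero-phase lowpass of an envelope
#'
#' Forward-backward 4th-order Butterworth lowpass (zero net phase).
#'
#' @param env A `trf_ts` envelope.
#' @param cutoff Cutoff frequency in Hz (default 9; must be < `fs/2`).
#' @param order Butterworth order applied in each direction (default 4).
#' @return Filtered `trf_ts`.
#' @export
lowpass_envelope <- function(env, cutoff = 9, order = 4L) {
  assert_ts(env, "env")
  if (cutoff <= 0 || cutoff >= env$fs / 2) stop_invalid("`cutoff` must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff / (env$fs / 2), type = "low")
  map_channels(env, function(x) {
    # odd-reflection padding suppresses forward-backward edge transients
    n <- length(x)
    np <- min(n - 1L, as.integer(ceiling(6 * env$fs / cutoff)))
    xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
    as.numeric(signal::filtfilt(bf, xp))[(np + 1L):(np + n)]
  })
}

#' Audio-to-envelope feature chain
#'
#' The full stimulus feature path: gammatone envelope at the audio rate,
#' FFT downsampling to the EEG rate, then a zero-phase lowpass.
#' Z-normalization is left to cross-validation (training statistics only).
#'
#' @param audio Single-channel `trf_ts` audio.
#' @param target_fs EEG sampling rate to land on (default 64 Hz).
#' @param lp_cutoff Post-resampling lowpass cutoff in Hz (default 9).
#' @param ... Passed to [gammatone_envelope()].
#' @return One-channel `trf_ts` envelope at `target_fs`.
#' @export
audio_to_envelope <- function(audio, target_fs = 64, lp_cutoff = 9, ...) {
  env <- gammatone_envelope(audio, ...)
  env <- fft_resample(env, target_fs)
  lowpass_envelope(env, cutoff = lp_cutoff)
}
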