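# TimeSeries container: a sampled multichannel signal with a sampling rate.

#' Create a multichannel time series
#'
#' The basic signal container used throughout the package.  `samples` holds
#' one row per time sample and one column per channel; `fs` is the sampling
#' rate in Hz.  EEG, EOG, audio, and envelopes all travel in this container.
#'
#' @param samples Numeric matrix (time x channels) or a vector for a single
#'   channel.  All values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector, one label per column.
#' @return An object of class `trf_ts` with fields `samples`, `fs`, `labels`.
#' @examples
#' ts <- time_series(cbind(sin(1:100), cos(1:100)), fs = 64)
#' n_samples(ts); n_channels(ts)
#' @export
time_series <- function(samples, fs, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_invalid("`fs` must be a single positive number (Hz)")
  }
  if (nrow(samples) == 0L || ncol(samples) == 0L) {
    stop_invalid("time series must contain at least one sample and one channel")
  }
  if (!all(is.finite(samples))) {
    stop_invalid("time series samples must all be finite")
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop_invalid("number of channel labels (", length(channel_labels),
                 ") must equal number of channels (", ncol(samples), ")")
  }
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, labels = as.character(channel_labels)),
            class = "trf_ts")
}

#' @export
print.trf_ts <- function(x, ...) {
  cat(sprintf("<trf_ts> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' @rdname time_series
#' @param ts A `trf_ts` object.
#' @export
n_samples <- function(ts) nrow(ts$samples)

#' @rdname time_series
#' @export
n_channels <- function(ts) ncol(ts$samples)

is_time_series <- function(x) inherits(x, "trf_ts")

assert_ts <- function(x, arg = "ts") {
  if (!is_time_series(x)) stop_invalid("`", arg, "` must be a trf_ts object")
  x
}

#' Read/write a delimited time series
#'
#' Plain-text interchange format: tab-separated values, one row per sample,
#' a header row of channel labels, and a leading comment line `# fs=<Hz>`
#' recording the sampling rate.
#'
#' @param path File path.
#' @param ts A `trf_ts` object (for writing).
#' @param fs Sampling rate override when the file has no `# fs=` line.
#' @return `read_timeseries_tsv()` returns a `trf_ts`;
#'   `write_timeseries_tsv()` returns `path` invisibly.
#' @export
read_timeseries_tsv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*fs\\s*=", first)) {
    fs_file <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
    if (is.null(fs)) fs <- fs_file
  }
  if (is.null(fs)) stop_invalid("no `# fs=` header in ", path, " and no `fs` given")
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  time_series(as.matrix(dat), fs = fs, channel_labels = colnames(dat))
}

#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(ts, path) {
  assert_ts(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", ts$fs), con)
  utils::write.table(ts$samples, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a mono or multichannel WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/24/32-bit integer) and
#' 32/64-bit IEEE float audio.  Integer samples are rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A `trf_ts` at the file's sampling rate, one column per channel.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid(path, " is not a RIFF file")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid(path, " is not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        channels  = readBin(fmt_raw[3:4], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        fs        = readBin(fmt_raw[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1L, size = 2L, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_invalid("incomplete WAV file: ", path)
  bytes <- fmt$bits %/% 8L
  n_tot <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 8L) {
        (as.numeric(readBin(data_raw, "integer", n_tot, size = 1L, signed = FALSE)) - 128) / 128
      } else if (fmt$bits == 24L) {
        b <- matrix(as.integer(data_raw), nrow = 3L)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      } else {
        readBin(data_raw, "integer", n_tot, size = bytes, endian = "little") /
          2^(fmt$bits - 1L)
      }
    },
    "3" = readBin(data_raw, "double", n_tot, size = bytes, endian = "little"),
    stop_invalid("unsupported WAV format code ", fmt$format)
  )
  m <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  time_series(m, fs = fmt$fs,
              channel_labels = paste0("audio", seq_len(fmt$channels)))
}
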