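#' Recording ingestion, epoching and performance metrics
#'
#' A raw recording is a samples-by-channels matrix at a nominal sampling
#' rate (12-bit integer amplitude range by convention).  The codec operates
#' on non-overlapping epochs of `N` samples per channel; each epoch is
#' demeaned per channel before sensing and the removed means travel in the
#' compressed header so the server can restore them.
#'
#' @name io
NULL

#' Construct a raw multichannel recording
#'
#' Wraps a samples-by-channels matrix together with its sampling rate and
#' channel labels.  Dead channels (identically zero) carry no information
#' and are dropped with a warning; they occur in practice when an electrode
#' is disconnected.
#'
#' @param samples numeric matrix, `T x C` (rows are time samples).
#' @param fs sampling rate in Hz (default 128).
#' @param labels optional character vector of `C` channel names.
#' @param drop_dead drop identically-zero channels? Default `TRUE`.
#' @return An object of class `eeg_recording`: the matrix with attributes
#'   `fs` and `labels`.
#' @export
raw_recording <- function(samples, fs = 128, labels = NULL, drop_dead = TRUE) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("recording must have at least one sample and one channel")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(labels)) {
    labels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  }
  if (length(labels) != ncol(samples))
    stop("labels length must match channel count")
  if (drop_dead) {
    dead <- apply(samples, 2L, function(x) all(x == 0))
    if (any(dead)) {
      warning(sprintf("removed %d dead channel(s): %s",
                      sum(dead), paste(labels[dead], collapse = ", ")))
      samples <- samples[, !dead, drop = FALSE]
      labels <- labels[!dead]
      if (ncol(samples) == 0L) stop("all channels are dead")
    }
  }
  colnames(samples) <- labels
  structure(samples, fs = fs, labels = labels, class = c("eeg_recording", "matrix"))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "fs")))
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Expects a header row of channel labels and one row per time sample.
#' Optionally resamples to a target rate with a polyphase resampler.
#'
#' @param path file path of a CSV matrix (samples x channels).
#' @param fs sampling rate of the stored data in Hz.
#' @param resample_to optional target rate in Hz; when given, each channel
#'   is resampled with [signal::resample()] before epoching.
#' @inheritParams raw_recording
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, fs = 128, resample_to = NULL, drop_dead = TRUE) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.null(resample_to) && resample_to != fs) {
    m <- apply(m, 2L, function(x) signal::resample(x, p = resample_to, q = fs))
    fs <- resample_to
  }
  raw_recording(m, fs = fs, labels = colnames(df), drop_dead = drop_dead)
}

#' Write a (reconstructed) recording as delimited text
#'
#' @param rec matrix or `eeg_recording` (samples x channels).
#' @param path output file path.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(unclass(rec))
  names(df) <- attr(rec, "labels") %||% colnames(rec) %||%
    paste0("ch", seq_len(ncol(rec)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Minimal EDF (European Data Format) reader
#'
#' Reads a continuous EDF file into an `eeg_recording`.  Supports the plain
#' EDF layout (16-bit little-endian samples, one data record stream per
#' signal); EDF+ annotation channels are not interpreted.  All signals must
#' share one sampling rate.
#'
#' @param path EDF file path.
#' @param physical convert to physical units using the per-signal gain and
#'   offset from the header? Default `TRUE`.
#' @inheritParams raw_recording
#' @return An `eeg_recording`.
#' @export
read_recording_edf <- function(path, physical = TRUE, drop_dead = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdchar <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rdchar(8)                              # version
  rdchar(80); rdchar(80)                 # patient / recording id
  rdchar(8); rdchar(8)                   # start date / time
  header_bytes <- as.integer(rdchar(8))
  rdchar(44)                             # reserved
  n_records <- as.integer(rdchar(8))
  record_dur <- as.numeric(rdchar(8))
  ns <- as.integer(rdchar(4))
  if (is.na(ns) || ns < 1L) stop("invalid EDF header: no signals")
  labels <- vapply(seq_len(ns), function(i) rdchar(16), "")
  for (i in seq_len(ns)) rdchar(80)      # transducer
  for (i in seq_len(ns)) rdchar(8)       # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rdchar(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rdchar(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rdchar(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rdchar(8)), 0)
  for (i in seq_len(ns)) rdchar(80)      # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rdchar(8)), 0L)
  for (i in seq_len(ns)) rdchar(32)      # reserved
  if (length(unique(nsamp)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported")
  seek(con, header_bytes)
  out <- matrix(0, nrow = n_records * nsamp[1], ncol = ns)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- readBin(con, "integer", n = nsamp[s], size = 2L,
                   signed = TRUE, endian = "little")
      if (length(x) < nsamp[s]) stop("EDF file truncated")
      out[(r - 1L) * nsamp[s] + seq_len(nsamp[s]), s] <- x
    }
  }
  if (physical) {
    gain <- (phys_max - phys_min) / (dig_max - dig_min)
    off <- phys_min - gain * dig_min
    out <- sweep(sweep(out, 2L, gain, "*"), 2L, off, "+")
  }
  raw_recording(out, fs = nsamp[1] / record_dur, labels = labels,
                drop_dead = drop_dead)
}

#' Split a recording into non-overlapping epochs
#'
#' Returns the `floor(T/N)` complete windows of `N` samples per channel;
#' any trailing partial window is dropped.
#'
#' @param rec `eeg_recording` or samples-by-channels matrix.
#' @param N epoch length in samples (default 512).
#' @return List of `N x C` matrices.
#' @export
epoch_stream <- function(rec, N = 512L) {
  m <- unclass(rec)
  if (N < 2L) stop("N must be at least 2")
  if (nrow(m) < N) stop("recording shorter than one epoch")
  n_ep <- nrow(m) %/% N
  lapply(seq_len(n_ep), function(k) m[((k - 1L) * N + 1L):(k * N), , drop = FALSE])
}

#' Remove (and restore) per-channel means
#'
#' `demean()` subtracts each channel's mean and records it; `add_means()`
#' inverts the operation exactly.  The means travel in the compressed
#' header so the server can restore the signal baseline.
#'
#' @param e `N x C` epoch matrix.
#' @return `demean()`: an object of class `demeaned_epoch` with elements
#'   `Ftilde` (`N x C`, zero-mean columns) and `means` (length `C`).
#' @export
demean <- function(e) {
  e <- as.matrix(e)
  mu <- colMeans(e)
  structure(list(Ftilde = sweep(e, 2L, mu, "-"), means = mu),
            class = "demeaned_epoch")
}

#' @rdname demean
#' @param d a `demeaned_epoch`, or an `N x C` matrix when `means` is given.
#' @param means channel means to restore (taken from `d` when omitted).
#' @export
add_means <- function(d, means = NULL) {
  if (inherits(d, "demeaned_epoch")) {
    sweep(d$Ftilde, 2L, d$means, "+")
  } else {
    sweep(as.matrix(d), 2L, means, "+")
  }
}

#' Normalized mean square error
#'
#' `nmse(x, y) = ||x - y||^2 / ||x - mean(x)||^2`: 0 for a perfect
#' reconstruction, 1 when the reconstruction is no better than predicting
#' the mean of the original.  The mean of the original is removed in the
#' denominator so baseline offsets between recordings do not bias the
#' score.
#'
#' @param x original vector (or matrix, compared element-wise).
#' @param y reconstructed vector of the same length.
#' @return Non-negative scalar.
#' @export
nmse <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  den <- sum((x - mean(x))^2)
  if (den == 0) stop("zero denominator: x is constant")
  sum((x - y)^2) / den
}

#' Compression ratio from bit counts
#'
#' `CR = b / bhat` where `b` is the bit count of the original signal and
#' `bhat` that of its compressed form; `2` means half the bits.
#'
#' @param b original bit count (> 0).
#' @param bhat compressed bit count (> 0).
#' @return Positive scalar.
#' @export
compression_ratio <- function(b, bhat) {
  if (b <= 0 || bhat <= 0) stop("bit counts must be positive")
  b / bhat
}

# Raw bit budget of an epoch at the conventional 12 bits/sample.
raw_bits <- function(N, C, bits_per_sample = 12L) N * C * bits_per_sample
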