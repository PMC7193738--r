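## Preprocessing chain: per-channel zero-phase bandpass -> unit-power
## normalisation -> channel averaging, then epoch segmentation and
## expanding windows for the streaming analysis.

# round half away from zero, so sample counts are platform-stable
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# linear convolution via FFT; nextn keeps the transform length composite
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

#' Design the analysis bandpass filter
#'
#' Linear-phase windowed-sinc FIR bandpass (Hamming window). The default
#' order scales with the sampling rate to give roughly a 1 Hz transition
#' width (order 3300, length 3301, at 1 kHz), which keeps the 2.5 Hz lower
#' passband edge honest while attenuating DC and everything above ~55 Hz by
#' more than 40 dB.
#'
#' @param fs sampling rate, Hz.
#' @param lo,hi passband edges, Hz; `0 < lo < hi < fs/2`.
#' @param order filter order (even; length is `order + 1`). Default
#'   `round(3.3 * fs)` rounded to even.
#' @return numeric vector of filter coefficients (impulse response).
#' @export
design_bandpass_fir <- function(fs, lo, hi, order = NULL) {
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("need 0 < lo < hi < fs/2 (got lo=", lo, ", hi=", hi,
         ", fs/2=", fs / 2, ")")
  if (is.null(order)) order <- round(3.3 * fs)
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L  # even order -> integer delay
  signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass",
               window = signal::hamming(order + 1L))
}

#' Zero-phase FIR bandpass filter
#'
#' Filters `x` with the symmetric FIR from [design_bandpass_fir()] and
#' removes the filter's known group delay, so passband components come out
#' neither delayed nor phase-shifted (a single forward pass, not
#' forward-backward filtering, so the designed magnitude response applies
#' unsquared). Output length equals input length; the edges, where the
#' impulse response hangs over the ends of the series, are implicitly
#' zero-padded.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param lo,hi passband edges, Hz.
#' @param order FIR order, defaulting as in [design_bandpass_fir()].
#' @return filtered vector, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, lo = 2.5, hi = 50, order = NULL) {
  h <- design_bandpass_fir(fs, lo, hi, order)
  if (length(x) <= length(h))
    stop("series (", length(x), " samples) is not longer than the filter's ",
         "impulse response (", length(h), " taps); use a shorter filter ",
         "(smaller 'order') or a longer series")
  gd <- (length(h) - 1L) %/% 2L  # group delay of the symmetric filter
  conv_fft(as.numeric(x), as.numeric(h))[(gd + 1L):(gd + length(x))]
}

#' Mean signal power
#'
#' `P = (1/L) * sum(x^2)`: the time-average power of the series.
#'
#' @param x numeric vector, length >= 1.
#' @return non-negative scalar.
#' @export
signal_power <- function(x) {
  if (length(x) == 0L) stop("cannot compute power of an empty series")
  mean(x^2)
}

#' Normalize a series to unit power
#'
#' Divides by `sqrt(signal_power(x))` so the result has mean-square value 1.
#' Idempotent; errors on an all-zero (zero-power) input.
#'
#' @param x numeric vector.
#' @return rescaled vector with unit power.
#' @export
normalize_unit_power <- function(x) {
  p <- signal_power(x)
  if (p <= 0) stop("cannot normalize a zero-power series")
  x / sqrt(p)
}

#' Average channels into a single series
#'
#' Pointwise arithmetic mean across channels; expects each channel already
#' filtered and power-normalized so no channel's gain dominates.
#'
#' @param rec a [recording()] or a list of equal-length numeric vectors.
#' @return numeric vector, the channel mean.
#' @export
average_channels <- function(rec) {
  channels <- if (inherits(rec, "recording")) rec$channels else rec
  if (!is.list(channels) || length(channels) == 0L)
    stop("need at least one channel")
  lens <- vapply(channels, length, integer(1))
  if (any(lens != lens[1]))
    stop("channel length mismatch: ", paste(unique(lens), collapse = ", "))
  Reduce(`+`, channels) / length(channels)
}

#' Full preprocessing chain for one recording
#'
#' Per channel: zero-phase bandpass then unit-power normalisation; then the
#' channels are averaged into one series. Per-channel normalisation before
#' averaging removes each electrode's gain, so the chain is invariant to
#' rescaling any input channel.
#'
#' @param rec a [recording()].
#' @param lo,hi bandpass edges in Hz (defaults 2.5 and 50).
#' @param order optional FIR order override.
#' @return a one-channel [recording()] carrying the averaged unit-power
#'   series; `meta$preprocessed` is set to `TRUE`.
#' @export
preprocess_recording <- function(rec, lo = 2.5, hi = 50, order = NULL) {
  stopifnot(inherits(rec, "recording"))
  proc <- lapply(rec$channels, function(ch)
    normalize_unit_power(bandpass_zero_phase(ch, rec$fs, lo, hi, order)))
  avg <- average_channels(proc)
  meta <- rec$meta
  meta$preprocessed <- TRUE
  meta$band_hz <- c(lo, hi)
  recording(list(avg), fs = rec$fs, subject_id = rec$subject_id,
            condition = rec$condition, meta = meta)
}

#' Segment a series into fixed-length epochs
#'
#' Non-overlapping, contiguous epochs from t = 0; a trailing remainder
#' shorter than one epoch is discarded. A 40-min series cut into 3-min
#' epochs therefore yields 13 epochs with 60 s unused.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param epoch_length_min epoch length in minutes (> 0).
#' @return list of epochs, each a list with `samples`, `fs`, `start_s`,
#'   `epoch_index` (1-based).
#' @export
segment <- function(x, fs, epoch_length_min) {
  if (epoch_length_min <= 0) stop("epoch_length_min must be positive")
  len <- as.integer(round_half_up(epoch_length_min * 60 * fs))
  n <- length(x) %/% len
  if (n == 0L) {
    warning("series (", length(x), " samples) is shorter than one epoch (",
            len, " samples); returning no epochs")
    return(list())
  }
  lapply(seq_len(n), function(k) {
    i0 <- (k - 1L) * len
    list(samples = x[(i0 + 1L):(i0 + len)], fs = fs,
         start_s = i0 / fs, epoch_index = k)
  })
}

#' Expanding analysis windows
#'
#' Window k (k = 0, 1, 2, ...) covers the first
#' `round((init_s + k * step_s) * fs)` samples; emission stops at the end
#' of the series. Returns the window sizes by default (the streaming LPC
#' estimator consumes the series incrementally and never needs the prefixes
#' materialized); set `materialize = TRUE` to get the prefix vectors.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param init_s first window length in seconds; `init_s >= step_s > 0`.
#' @param step_s window growth per step, seconds.
#' @param materialize if `TRUE`, return a list of prefix vectors instead of
#'   an integer vector of sizes.
#' @return integer vector of window sizes, or list of numeric prefixes.
#' @export
expanding_windows <- function(x, fs, init_s = 1, step_s = 1,
                              materialize = FALSE) {
  if (!(init_s >= step_s && step_s > 0))
    stop("need init_s >= step_s > 0")
  L <- length(x)
  kmax <- floor((L / fs - init_s) / step_s)
  if (kmax < 0) return(if (materialize) list() else integer(0))
  sizes <- as.integer(round_half_up((init_s + (0:kmax) * step_s) * fs))
  sizes <- sizes[sizes <= L]
  if (!materialize) return(sizes)
  lapply(sizes, function(n) x[seq_len(n)])
}
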