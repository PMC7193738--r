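## Comparator biomarkers: Welch PSD / beta-band power, Kullback-Leibler
## phase-amplitude-coupling (PAC) modulation indices for single band pairs
## and for a 6 x 6 sub-band grid, and a canonical-correlation composite of
## the grid.

#' Frequency band specification
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return list of class `"band_spec"`.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(lo > 0 && lo < hi))
    stop("need 0 < lo < hi for band '", name, "'")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Canonical analysis bands
#'
#' `default_subbands()` returns the six 3-60 Hz sub-bands used for the PAC
#' grid (delta 3-4, theta 5-7, alpha 8-11, low beta 12-19, high beta
#' 20-30, gamma 31-60 Hz). `comparator_bands()` returns the named band
#' pairs of the single-pair comparators: beta power 12-30 Hz; beta-phase
#' 13-30 Hz with gamma-amplitude 50-200 Hz; low-beta-phase 12-30 Hz with
#' high-frequency-oscillation (HFO) amplitude 200-350 Hz.
#'
#' @return a named list of [band_spec()] objects.
#' @export
default_subbands <- function() {
  list(band_spec("delta", 3, 4), band_spec("theta", 5, 7),
       band_spec("alpha", 8, 11), band_spec("low_beta", 12, 19),
       band_spec("high_beta", 20, 30), band_spec("gamma", 31, 60))
}

#' @rdname default_subbands
#' @export
comparator_bands <- function() {
  list(beta = band_spec("beta", 12, 30),
       dehemptinne_phase = band_spec("beta_phase", 13, 30),
       dehemptinne_amp = band_spec("gamma_amp", 50, 200),
       lopez_phase = band_spec("low_beta_phase", 12, 30),
       lopez_amp = band_spec("hfo_amp", 200, 350))
}

#' Welch power spectral density
#'
#' One-sided PSD by averaging modified periodograms of Hamming-tapered,
#' 50%-overlapping segments. Density scaling: the integral of the PSD over
#' `(0, fs/2)` approximates the signal's mean power (Parseval).
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds (default 2 s, i.e. 0.5 Hz
#'   resolution).
#' @param overlap fractional overlap between segments in `[0, 1)`.
#' @return list with `freq` (Hz, from 0 to `fs/2`) and `psd`
#'   (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  n <- as.integer(round_half_up(window_s * fs))
  if (n < 4L) stop("window too short")
  if (n > length(x))
    stop("Welch window (", n, " samples) longer than series (",
         length(x), ")")
  w <- as.numeric(signal::hamming(n))
  step <- max(1L, as.integer(round(n * (1 - overlap))))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  nhalf <- n %/% 2L
  acc <- numeric(nhalf + 1L)
  for (s in starts) {
    X <- stats::fft(x[s:(s + n - 1L)] * w)
    acc <- acc + Mod(X[1:(nhalf + 1L)])^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist for even n)
  dbl <- rep(2, nhalf + 1L)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[nhalf + 1L] <- 1
  list(freq = (0:nhalf) * fs / n, psd = pxx * dbl)
}

#' Beta-band power fraction
#'
#' Fraction of total (0, fs/2) power lying in the given band, computed
#' from the Welch PSD. The default 12-30 Hz band is the beta rhythm used
#' as the conventional adaptive-stimulation trigger. Gain-invariant by
#' construction.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param band numeric `c(lo, hi)` in Hz or a [band_spec()].
#' @param window_s,overlap passed to [welch_psd()].
#' @return scalar in `[0, 1]`.
#' @export
beta_power <- function(x, fs, band = c(12, 30), window_s = 2, overlap = 0.5) {
  if (inherits(band, "band_spec")) band <- c(band$lo, band$hi)
  p <- welch_psd(x, fs, window_s, overlap)
  nonzero <- p$freq > 0
  inband <- p$freq >= band[1] & p$freq <= band[2]
  sum(p$psd[inband & nonzero]) / sum(p$psd[nonzero])
}

# analytic signal via the frequency-domain construction: negative
# frequencies zeroed, positive doubled; Im() is the Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# zero-phase FIR for a PAC band: order covers >= 3 cycles of the band's
# low edge
pac_band_filter <- function(x, fs, band) {
  order <- as.integer(ceiling(3 * fs / band$lo))
  if (order %% 2L == 1L) order <- order + 1L
  bandpass_zero_phase(x, fs, band$lo, band$hi, order = order)
}

# MI core on pre-extracted phase and envelope
mi_from_phase_amp <- function(phase, amp, nbins) {
  bins <- findInterval(phase, seq(-pi, pi, length.out = nbins + 1L),
                       rightmost.closed = TRUE, all.inside = TRUE)
  m <- vapply(seq_len(nbins), function(b) {
    sel <- bins == b
    if (any(sel)) mean(amp[sel]) else 0
  }, numeric(1))
  tot <- sum(m)
  if (tot <= 0) stop("amplitude envelope is identically zero")
  p <- m / tot
  nz <- p > 0
  (log(nbins) + sum(p[nz] * log(p[nz]))) / log(nbins)
}

#' Phase-amplitude coupling modulation index
#'
#' Kullback-Leibler modulation index: the instantaneous phase of the
#' phase-band-filtered series (analytic signal) is binned into `nbins`
#' equal bins; the mean amplitude envelope of the amplitude-band-filtered
#' series per bin, normalized to a distribution, is compared to the
#' uniform distribution by KL divergence and scaled by `log(nbins)` so
#' the index lies in `[0, 1]` (0 = no coupling, 1 = envelope concentrated
#' in one phase bin). Invariant to rescaling of the input.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param phase_band,amp_band [band_spec()] objects (or `c(lo, hi)`
#'   vectors) for the modulating phase and modulated amplitude bands.
#' @param nbins number of phase bins (default 18, i.e. 20 degrees).
#' @return scalar modulation index in `[0, 1]`.
#' @export
pac_mi <- function(x, fs, phase_band, amp_band, nbins = 18L) {
  if (is.numeric(phase_band))
    phase_band <- band_spec("phase", phase_band[1], phase_band[2])
  if (is.numeric(amp_band))
    amp_band <- band_spec("amp", amp_band[1], amp_band[2])
  if (amp_band$hi >= fs / 2)
    stop("amplitude band upper edge (", amp_band$hi,
         " Hz) must lie below Nyquist (", fs / 2, " Hz)")
  if (length(x) / fs < 10 / phase_band$lo)
    stop("series too short: need >= 10 cycles of the ", phase_band$lo,
         " Hz phase-band edge (", round(10 / phase_band$lo, 2), " s)")
  xp <- pac_band_filter(x, fs, phase_band)
  xa <- pac_band_filter(x, fs, amp_band)
  if (mean(xa^2) < 1e-5 * mean(x^2))
    warning("amplitude-band ", amp_band$lo, "-", amp_band$hi,
            " Hz power is below 1e-5 of the signal power; the band is ",
            "effectively empty and the modulation index reflects noise")
  mi_from_phase_amp(Arg(analytic_signal(xp)), Mod(analytic_signal(xa)),
                    nbins)
}

#' PAC modulation-index grid
#'
#' Computes the modulation index for every (phase band, amplitude band)
#' pair drawn from `bands` - with the default six 3-60 Hz sub-bands, a
#' 6 x 6 = 36-cell grid per signal. Each band is filtered once and reused
#' on both axes.
#'
#' @param signals a numeric vector or a list of numeric vectors.
#' @param fs sampling rate, Hz.
#' @param bands list of [band_spec()] (default [default_subbands()]).
#' @param nbins phase bins, as in [pac_mi()].
#' @return list of `"pac_grid_result"` objects, one per signal, each with
#'   `mi` (matrix, phase bands in rows, amplitude bands in columns) and
#'   `bands` (the band names).
#' @export
pac_grid <- function(signals, fs, bands = default_subbands(), nbins = 18L) {
  if (is.numeric(signals)) signals <- list(signals)
  nb <- length(bands)
  nms <- vapply(bands, function(b) b$name, character(1))
  lapply(signals, function(x) {
    filt <- lapply(bands, function(b) pac_band_filter(x, fs, b))
    phases <- lapply(filt, function(f) Arg(analytic_signal(f)))
    amps <- lapply(filt, function(f) Mod(analytic_signal(f)))
    mi <- matrix(NA_real_, nb, nb, dimnames = list(phase = nms, amp = nms))
    for (i in seq_len(nb))
      for (j in seq_len(nb))
        mi[i, j] <- mi_from_phase_amp(phases[[i]], amps[[j]], nbins)
    structure(list(mi = mi, bands = nms), class = "pac_grid_result")
  })
}

#' Canonical-correlation composite of PAC grids
#'
#' Projects each signal's vector of modulation indices onto the first
#' canonical direction between the MI feature block and a two-condition
#' indicator, yielding one composite coupling index per signal. With a
#' single binary indicator this is a discriminant direction; it requires
#' more signals than MI features. The sign is fixed so the second
#' condition level has the larger mean composite.
#'
#' @param mi_matrix numeric matrix, signals in rows, MI features (e.g. the
#'   36 grid cells) in columns. A list of `"pac_grid_result"` objects is
#'   also accepted and flattened row-wise.
#' @param labels condition label per signal (two levels).
#' @return list with `weights` (per feature), `composite` (per signal),
#'   `cor` (first canonical correlation), `levels`.
#' @export
cca_composite <- function(mi_matrix, labels) {
  if (is.list(mi_matrix) && !is.matrix(mi_matrix))
    mi_matrix <- do.call(rbind, lapply(mi_matrix, function(g) as.numeric(g$mi)))
  mi_matrix <- as.matrix(mi_matrix)
  n <- nrow(mi_matrix); p <- ncol(mi_matrix)
  if (n <= p)
    stop("the total number of signals must be greater than the number of ",
         "PAC measurements (have ", n, " signals for ", p, " features)")
  labels <- as.factor(labels)
  if (length(labels) != n) stop("one label per signal required")
  if (nlevels(labels) != 2L) stop("exactly two condition levels required")
  Xc <- scale(mi_matrix, center = TRUE, scale = FALSE)
  if (qr(Xc)$rank < p)
    stop("MI feature block is rank-deficient; cannot form a unique ",
         "canonical direction")
  y <- as.numeric(labels == levels(labels)[2])
  cc <- stats::cancor(mi_matrix, matrix(y, ncol = 1))
  w <- cc$xcoef[, 1]
  composite <- as.numeric(Xc %*% w)
  if (mean(composite[y == 1]) < mean(composite[y == 0])) {
    w <- -w
    composite <- -composite
  }
  list(weights = w, composite = composite, cor = cc$cor[1],
       levels = levels(labels))
}
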