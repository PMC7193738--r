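## Synthetic LFP simulator: multi-channel, 1 kHz, 40-min sessions in two
## conditions that differ in dominant frequency and spectral bandwidth
## (encoded as AR(2) pole frequency and pole radius), plus coupled test
## signals for the PAC comparators.

#' Synthetic session specification
#'
#' Parameters of one simulated LFP session. The shared neural source is an
#' AR(2) process with a conjugate pole pair at radius `pole_radius` and
#' frequency `f0_hz`: the radius sets the spectral bandwidth (closer to 1 =
#' narrower peak) and the pole phase sets the dominant frequency. Channels
#' add independent Gaussian sensor noise at `snr_db`.
#'
#' @param fs sampling rate, Hz (default 1000).
#' @param duration_min session length in minutes (default 40).
#' @param n_channels electrode channels sharing the source (default 4).
#' @param pole_radius AR(2) pole radius `A`, in (0, 1).
#' @param f0_hz dominant frequency, `0 < f0 < fs/2`.
#' @param snr_db source-to-channel-noise ratio in dB; `Inf` = noise-free.
#' @param seed integer RNG seed for this session.
#' @return list of class `"synth_spec"`.
#' @export
synth_spec <- function(fs = 1000, duration_min = 40, n_channels = 4,
                       pole_radius = 0.99, f0_hz = 13, snr_db = 10,
                       seed = 1L) {
  if (!(pole_radius > 0 && pole_radius < 1))
    stop("pole_radius must lie in (0, 1) for a stationary source (got ",
         pole_radius, ")")
  if (!(f0_hz > 0 && f0_hz < fs / 2))
    stop("f0_hz must lie in (0, fs/2)")
  if (duration_min <= 0 || n_channels < 1) stop("invalid duration or channels")
  structure(list(fs = fs, duration_min = duration_min,
                 n_channels = as.integer(n_channels),
                 pole_radius = pole_radius, f0_hz = f0_hz,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default two-condition generative parameters
#'
#' The study conditions the simulator emulates: a "saline-like" narrowband
#' source (pole radius 0.995, dominant frequency 12.2 Hz) and a
#' "levodopa-like" broader source at higher frequency (radius 0.985,
#' 14.2 Hz), both 4-channel, 40-min, 1 kHz sessions at 10 dB channel SNR.
#'
#' @param seed base seed stored in both specs (per-session seeds are
#'   derived from it by [gen_condition_pair()]).
#' @return named list with elements `saline` and `levodopa`, each a
#'   [synth_spec()].
#' @export
default_condition_specs <- function(seed = 1L) {
  list(saline = synth_spec(pole_radius = 0.995, f0_hz = 12.2, seed = seed),
       levodopa = synth_spec(pole_radius = 0.985, f0_hz = 14.2, seed = seed))
}

#' Generate an AR(2) source realization
#'
#' `x(n) = a1 x(n-1) + a2 x(n-2) + e(n)` with `a1 = 2 A cos(2 pi f0/fs)`,
#' `a2 = -A^2` and unit-variance Gaussian innovations. The first
#' `ceiling(10 / (1 - A))` samples are discarded as burn-in so the output
#' is (approximately) a stationary draw.
#'
#' @param spec a [synth_spec()].
#' @param seed seed used before drawing (default the spec's); `NULL`
#'   continues the caller's RNG stream.
#' @return numeric vector of `duration_min * 60 * fs` samples.
#' @export
gen_ar2_source <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(seed)) set.seed(seed)
  A <- spec$pole_radius
  n <- as.integer(round_half_up(spec$duration_min * 60 * spec$fs))
  burn <- as.integer(ceiling(10 / (1 - A)))
  a <- c(2 * A * cos(2 * pi * spec$f0_hz / spec$fs), -A^2)
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, a, method = "recursive"))
  x[(burn + 1L):(burn + n)]
}

#' Generate one multi-channel synthetic session
#'
#' One shared AR(2) source plus independent per-channel Gaussian noise
#' scaled to `snr_db`, so all channels carry the same spectral signature
#' under uncorrelated sensor noise.
#'
#' @param spec a [synth_spec()].
#' @param subject_id,condition labels stored on the [recording()].
#' @return a [recording()] with `n_channels` channels.
#' @export
gen_session <- function(spec, subject_id = "sim", condition = "sim") {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  src <- gen_ar2_source(spec, seed = NULL)
  noise_sd <- if (is.infinite(spec$snr_db)) 0
              else stats::sd(src) * 10^(-spec$snr_db / 20)
  channels <- lapply(seq_len(spec$n_channels), function(ch) {
    if (noise_sd == 0) src else src + stats::rnorm(length(src), sd = noise_sd)
  })
  recording(channels, fs = spec$fs, subject_id = subject_id,
            condition = condition,
            meta = list(pole_radius = spec$pole_radius, f0_hz = spec$f0_hz,
                        snr_db = spec$snr_db, seed = spec$seed))
}

# fixed counter scheme: session k of a dataset seeded with `seed` draws
# from seed + 7919 * k (mod 2^31 - 1), so generation order never matters
session_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * counter) %% 2147483647)
}

#' Per-session specs for a two-condition dataset
#'
#' Expands a pair of condition-level [synth_spec()]s into one spec per
#' (subject, condition) with deterministic per-session seeds, without
#' generating any samples - callers that want to keep memory flat can
#' stream sessions one at a time through [gen_session()].
#'
#' @param n_subjects subjects per condition (paired design: each subject
#'   has both conditions).
#' @param saline_spec,levodopa_spec condition-level [synth_spec()]s
#'   (defaults from [default_condition_specs()]).
#' @param seed master seed for the dataset.
#' @return data-frame-free list: one element per session with `spec`,
#'   `subject_id`, `condition`.
#' @export
condition_pair_specs <- function(n_subjects = 4,
                                 saline_spec = default_condition_specs()$saline,
                                 levodopa_spec = default_condition_specs()$levodopa,
                                 seed = 1L) {
  out <- list()
  counter <- 0L
  for (s in seq_len(n_subjects)) {
    for (cond in c("saline", "levodopa")) {
      counter <- counter + 1L
      spec <- if (cond == "saline") saline_spec else levodopa_spec
      spec$seed <- session_seed(seed, counter)
      out[[counter]] <- list(spec = spec,
                             subject_id = paste0("subj", s),
                             condition = cond)
    }
  }
  out
}

#' Generate a two-condition dataset of sessions
#'
#' Materializes every session of [condition_pair_specs()]: `2 *
#' n_subjects` recordings. With the 40-min defaults and 3-min epochs this
#' yields 13 epochs per session and 52 per condition.
#'
#' @inheritParams condition_pair_specs
#' @return list of [recording()]s.
#' @export
gen_condition_pair <- function(n_subjects = 4,
                               saline_spec = default_condition_specs()$saline,
                               levodopa_spec = default_condition_specs()$levodopa,
                               seed = 1L) {
  lapply(condition_pair_specs(n_subjects, saline_spec, levodopa_spec, seed),
         function(s) gen_session(s$spec, s$subject_id, s$condition))
}

#' Generate a phase-amplitude-coupled test signal
#'
#' `s(t) = cos(2 pi f_phase t) + 0.5 (1 + depth cos(2 pi f_phase t))
#' cos(2 pi f_amp t) + noise`: a slow carrier whose phase modulates the
#' envelope of a fast oscillation with modulation `depth`, the standard
#' construction for validating PAC estimators.
#'
#' @param fs sampling rate, Hz.
#' @param duration_s length in seconds.
#' @param f_phase,f_amp slow and fast frequencies, `f_phase < f_amp <
#'   fs/2`.
#' @param depth modulation depth in `[0, 1]`; 0 = no coupling.
#' @param noise_sd standard deviation of added Gaussian noise.
#' @param seed RNG seed.
#' @return numeric vector of `duration_s * fs` samples.
#' @export
gen_pac_signal <- function(fs, duration_s, f_phase, f_amp, depth = 0.8,
                           noise_sd = 0.1, seed = 1L) {
  if (!(f_amp > f_phase)) stop("need f_amp > f_phase")
  if (!(f_amp < fs / 2)) stop("f_amp must lie below Nyquist (fs/2)")
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  set.seed(seed)
  t <- seq(0, by = 1 / fs, length.out = as.integer(round_half_up(duration_s * fs)))
  slow <- cos(2 * pi * f_phase * t)
  fast <- cos(2 * pi * f_amp * t)
  slow + 0.5 * (1 + depth * slow) * fast +
    stats::rnorm(length(t), sd = noise_sd)
}
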