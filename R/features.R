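## Feature-extraction pipeline: one scalar per epoch per method, collected
## into a feature_table for the separation layer.

feature_methods <- c("lpc1", "lpc2_freq", "beta", "pac_dehemptinne",
                     "pac_lopez")

# scalar feature for one epoch of a prepared series
epoch_feature <- function(x, fs, method) {
  bands <- comparator_bands()
  switch(method,
    lpc1 = separation_feature(fit_lpc(x, fs, 1L)),
    lpc2_freq = fit_lpc(x, fs, 2L)$dominant_freq_hz,
    beta = beta_power(x, fs, bands$beta),
    pac_dehemptinne = pac_mi(x, fs, bands$dehemptinne_phase,
                             bands$dehemptinne_amp),
    pac_lopez = pac_mi(x, fs, bands$lopez_phase, bands$lopez_amp),
    stop("unknown method '", method, "'; available: ",
         paste(feature_methods, collapse = ", ")))
}

# one averaged series per method family: LPC features run on the full
# preprocessing chain (2.5-50 Hz zero-phase bandpass, unit power,
# average); spectral/PAC comparators run on the normalized average
# without the bandpass, since their amplitude bands extend above 50 Hz
prepared_series <- function(rec, method, band = c(2.5, 50)) {
  if (startsWith(method, "lpc")) {
    if (isTRUE(rec$meta$preprocessed)) rec$channels[[1]]
    else preprocess_recording(rec, band[1], band[2])$channels[[1]]
  } else {
    average_channels(lapply(rec$channels, normalize_unit_power))
  }
}

#' Extract per-epoch features from a set of sessions
#'
#' For each session: prepares the single averaged series appropriate to
#' the method (full bandpass chain for LPC features; normalized average
#' without the analysis bandpass for the spectral and coupling
#' comparators), segments it into epochs, and computes one scalar per
#' epoch.
#'
#' Methods: `"lpc1"` (first-order separation feature
#' `(1 - a1) * 1e3`), `"lpc2_freq"` (dominant frequency from the
#' second-order poles, Hz), `"beta"` (12-30 Hz power fraction),
#' `"pac_dehemptinne"` (13-30 Hz phase / 50-200 Hz amplitude modulation
#' index), `"pac_lopez"` (12-30 Hz phase / 200-350 Hz HFO amplitude
#' modulation index).
#'
#' A recording whose `meta$preprocessed` flag is set (the output of
#' [preprocess_recording()]) is used as-is for the LPC methods, so one
#' preprocessing pass can serve several epoch lengths.
#'
#' @param sessions a [recording()] or list of recordings.
#' @param methods character vector of method names (see above).
#' @param epoch_min epoch length in minutes.
#' @param band preprocessing bandpass edges for the LPC chain, Hz.
#' @return a [feature_table()] with one row per session x epoch x method.
#' @export
extract_features <- function(sessions, methods = "lpc1", epoch_min = 3,
                             band = c(2.5, 50)) {
  if (inherits(sessions, "recording")) sessions <- list(sessions)
  methods <- match.arg(methods, feature_methods, several.ok = TRUE)
  rows <- list()
  for (rec in sessions) {
    for (method in methods) {
      x <- prepared_series(rec, method, band)
      eps <- segment(x, rec$fs, epoch_min)
      for (ep in eps) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subject_id, condition = rec$condition,
          epoch_index = ep$epoch_index,
          epoch_length_s = epoch_min * 60,
          method = method,
          value = epoch_feature(ep$samples, rec$fs, method),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(feature_table())
  validate_feature_table(do.call(rbind, rows))
}

#' PAC-grid composite features across a session set
#'
#' Runs the 36-cell PAC grid on every epoch of every session, then
#' projects each epoch's MI vector onto the first canonical direction
#' against the condition indicator ([cca_composite()]). The weights are
#' fitted on the whole collection (the method is inherently
#' dataset-level: it needs more epochs than MI features), so the
#' composite is a pooled, data-dependent index.
#'
#' @param sessions list of [recording()]s covering two conditions.
#' @param epoch_min epoch length in minutes.
#' @param bands PAC sub-bands (default [default_subbands()]).
#' @return a [feature_table()] with method `"pac_grid_cca"`, plus
#'   attributes `weights` and `cor` from the canonical fit.
#' @export
pac_grid_features <- function(sessions, epoch_min = 3,
                              bands = default_subbands()) {
  if (inherits(sessions, "recording")) sessions <- list(sessions)
  meta <- list(); mats <- list()
  for (rec in sessions) {
    x <- average_channels(lapply(rec$channels, normalize_unit_power))
    eps <- segment(x, rec$fs, epoch_min)
    grids <- pac_grid(lapply(eps, `[[`, "samples"), rec$fs, bands)
    for (i in seq_along(eps)) {
      mats[[length(mats) + 1L]] <- as.numeric(grids[[i]]$mi)
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, condition = rec$condition,
        epoch_index = eps[[i]]$epoch_index,
        epoch_length_s = epoch_min * 60,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  cc <- cca_composite(do.call(rbind, mats), meta$condition)
  tab <- validate_feature_table(cbind(
    meta, method = "pac_grid_cca", value = cc$composite))
  attr(tab, "weights") <- cc$weights
  attr(tab, "cor") <- cc$cor
  tab
}
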