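## Linear predictive coding: biased autocorrelation, Yule-Walker solution,
## Levinson-Durbin recursion, second-order pole analysis, AR-model PSD, and
## a constant-cost streaming estimator for expanding-window (real-time) use.

#' Biased sample autocorrelation
#'
#' Computes `r(l) = (1/L) * sum_{n=l}^{L-1} x(n) x(n-l)` for lags
#' `0..maxlag`. Dividing by `L` (not `L - l`) is the standard LPC
#' convention: it guarantees the Toeplitz autocorrelation matrix is
#' positive semidefinite, so the Levinson-Durbin recursion is well posed.
#'
#' @param x numeric sample vector (real-valued).
#' @param maxlag largest lag, `0 <= maxlag < length(x)`.
#' @return object of class `"autocorr_set"`: list with `lags` (values
#'   `r(0)..r(maxlag)`), `L` (samples used), `estimator = "biased"`.
#' @export
autocorr <- function(x, maxlag) {
  L <- length(x)
  if (maxlag < 0 || maxlag >= L)
    stop("need 0 <= maxlag < length(x) (maxlag=", maxlag, ", L=", L, ")")
  x <- as.numeric(x)
  lags <- vapply(0:maxlag, function(l)
    sum(x[(l + 1L):L] * x[1:(L - l)]) / L, numeric(1))
  structure(list(lags = lags, L = L, estimator = "biased"),
            class = "autocorr_set")
}

ac_lags <- function(ac) {
  if (inherits(ac, "autocorr_set")) ac$lags else as.numeric(ac)
}

#' Solve the Yule-Walker equations directly
#'
#' Builds the N x N Toeplitz autocorrelation matrix from lags `0..N-1` and
#' solves it against lags `1..N` by direct inversion. This is the
#' reference route; [levinson_durbin()] obtains the same coefficients
#' order-recursively.
#'
#' @param ac an `autocorr_set` (or plain numeric vector `r(0)..r(maxlag)`)
#'   with lags through `N`.
#' @param N model order, >= 1.
#' @return numeric coefficient vector `a` of length `N` in the predictor
#'   convention `x_hat(n) = sum_k a_k x(n-k)`.
#' @export
yule_walker <- function(ac, N) {
  r <- ac_lags(ac)
  if (N < 1L) stop("order N must be >= 1")
  if (length(r) < N + 1L)
    stop("need autocorrelation lags through N=", N,
         " (have ", length(r) - 1L, ")")
  R <- stats::toeplitz(r[1:N])
  rc <- rcond(R)
  if (!is.finite(rc) || rc < 1e-12)
    stop("autocorrelation matrix is numerically singular ",
         "(reciprocal condition number ", format(rc), "); ",
         "the series may be constant or perfectly predictable")
  as.numeric(solve(R, r[2:(N + 1L)]))
}

#' Levinson-Durbin recursion
#'
#' Order-recursive solver for the Yule-Walker system: from the order-(m-1)
#' solution it produces the order-m coefficients and residual in O(m)
#' operations, yielding every intermediate order along the way. The
#' residual satisfies `J_m = r(0) * prod(1 - k_i^2)` and is non-increasing
#' in the order.
#'
#' @param ac an `autocorr_set` (or numeric lag vector) with lags through `N`.
#' @param N highest model order.
#' @return list with `coeffs` (list; element m is the order-m coefficient
#'   vector `a^m`), `residuals` (numeric, `J_1..J_N`), `reflection`
#'   (numeric, `k_1..k_N`), `r0`.
#' @export
levinson_durbin <- function(ac, N) {
  r <- ac_lags(ac)
  if (N < 1L) stop("order N must be >= 1")
  if (length(r) < N + 1L)
    stop("need autocorrelation lags through N=", N)
  r0 <- r[1]
  if (!(r0 > 0)) stop("r(0) must be positive (zero-power series?)")
  coeffs <- vector("list", N)
  J <- numeric(N)
  k <- numeric(N)
  a <- numeric(0)
  Jprev <- r0
  for (m in seq_len(N)) {
    acc <- if (m == 1L) 0 else sum(a * r[m:2])
    km <- (r[m + 1L] - acc) / Jprev
    if (!is.finite(km) || abs(km) >= 1)
      stop("reflection coefficient |k_", m, "| >= 1 (", format(km),
           "): autocorrelation sequence is not numerically ",
           "positive definite")
    a <- if (m == 1L) km else c(a - km * rev(a), km)
    Jprev <- Jprev * (1 - km^2)
    coeffs[[m]] <- a
    J[m] <- Jprev
    k[m] <- km
  }
  list(coeffs = coeffs, residuals = J, reflection = k, r0 = r0)
}

#' Fit an LPC (autoregressive) model
#'
#' Estimates the order-`N` predictor `x_hat(n) = sum_k a_k x(n-k)` by the
#' biased autocorrelation method ([autocorr()] + [levinson_durbin()]).
#' For `N = 2` the characteristic poles, their radius and the dominant
#' frequency they encode are attached.
#'
#' @param x numeric sample vector (ideally preprocessed to unit power).
#' @param fs sampling rate, Hz.
#' @param order model order; the analysis pipeline uses 1 or 2, higher
#'   orders are accepted.
#' @return object of class `"lpc_model"`: `order`, `coeffs`, `residual`
#'   (mean-square prediction error `J`), `r0`, `fs`, and for order 2
#'   `poles` (complex pair), `pole_radius`, `dominant_freq_hz` (`NA` when
#'   the poles are real).
#' @examples
#' set.seed(1)
#' e <- rnorm(5000)
#' x <- as.numeric(stats::filter(e, 0.9, method = "recursive"))
#' fit_lpc(x, fs = 1000, order = 1)$coeffs  # close to 0.9
#' @export
fit_lpc <- function(x, fs, order = 1L) {
  ac <- autocorr(x, order)
  ld <- levinson_durbin(ac, order)
  model <- structure(
    list(order = as.integer(order), coeffs = ld$coeffs[[order]],
         residual = ld$residuals[order], reflection = ld$reflection,
         r0 = ld$r0, fs = fs,
         poles = NULL, pole_radius = NA_real_, dominant_freq_hz = NA_real_),
    class = "lpc_model")
  if (order == 2L) {
    p <- poles_of_order2(model$coeffs)
    model$poles <- p
    model$pole_radius <- Mod(p[1])
    model$dominant_freq_hz <- dominant_frequency(p, fs)
  }
  model
}

#' @export
print.lpc_model <- function(x, ...) {
  cat(sprintf("<lpc_model> order %d @ %g Hz\n", x$order, x$fs))
  cat("  coeffs:  ", paste(format(x$coeffs, digits = 6), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  residual J = %s (r0 = %s)\n",
              format(x$residual, digits = 6), format(x$r0, digits = 6)))
  if (x$order == 2L) {
    cat(sprintf("  poles: %s; radius %.5f; dominant freq %s Hz\n",
                paste(format(x$poles, digits = 5), collapse = ", "),
                x$pole_radius,
                if (is.na(x$dominant_freq_hz)) "none"
                else format(x$dominant_freq_hz, digits = 5)))
  }
  invisible(x)
}

#' Poles of a second-order LPC model
#'
#' Roots of `z^2 - a1 z - a2`, the characteristic polynomial of the
#' order-2 predictor. The roots form a complex-conjugate pair exactly when
#' `a1^2 + 4 a2 < 0`; for `a = (2 A cos(theta), -A^2)` they are
#' `A exp(+/- i theta)`.
#'
#' @param coeffs numeric vector `c(a1, a2)`.
#' @return complex vector of length 2.
#' @export
poles_of_order2 <- function(coeffs) {
  if (length(coeffs) != 2L) stop("need exactly two coefficients (a1, a2)")
  a1 <- coeffs[1]; a2 <- coeffs[2]
  disc <- a1^2 + 4 * a2
  if (disc < 0) {
    re <- a1 / 2
    im <- sqrt(-disc) / 2
    complex(real = c(re, re), imaginary = c(im, -im))
  } else {
    s <- sqrt(disc)
    as.complex(c((a1 + s) / 2, (a1 - s) / 2))
  }
}

#' Dominant frequency from a conjugate pole pair
#'
#' A conjugate pair `A exp(+/- i 2 pi f0 Ts)` encodes a spectral peak at
#' `f0 = |arg(p)| * fs / (2 pi)`. Real distinct poles carry no oscillatory
#' component, so `NA` ("none") is returned; a coincident negative real
#' pair is the Nyquist limit and returns `fs/2`.
#'
#' @param poles complex vector of length 2 from [poles_of_order2()].
#' @param fs sampling rate, Hz.
#' @return frequency in Hz, or `NA_real_` for real poles.
#' @export
dominant_frequency <- function(poles, fs) {
  if (length(poles) != 2L) stop("need a pole pair")
  if (abs(Im(poles[1])) > 0) return(abs(Arg(poles[1])) * fs / (2 * pi))
  re <- Re(poles)
  if (re[1] < 0 && abs(re[1] - re[2]) <= 1e-12 * max(1, abs(re[1])))
    return(fs / 2)
  NA_real_
}

#' Scalar separation feature from a first-order model
#'
#' The classification scalar `delta = (1 - a1) * 1e3`. Low-pass-dominated
#' LFP gives `a1` just below +1 in this predictor convention, so `delta`
#' is small and positive; broader-band signals decorrelate faster at lag
#' one, lowering `a1` and raising `delta`. The `1e3` scale puts typical
#' values in the units used on comparison plots.
#'
#' @param model an order-1 `"lpc_model"`, or a bare numeric `a1`.
#' @return numeric scalar `delta`.
#' @export
separation_feature <- function(model) {
  a1 <- if (inherits(model, "lpc_model")) {
    if (model$order != 1L) stop("separation_feature needs an order-1 model")
    model$coeffs[1]
  } else as.numeric(model)[1]
  (1 - a1) * 1e3
}

#' Power spectral density of a fitted AR model
#'
#' `S(f) = J * Ts / |1 - sum_k a_k exp(-i 2 pi f k Ts)|^2` on the given
#' frequency grid, the model-implied (all-pole) spectrum.
#'
#' @param model an `"lpc_model"`.
#' @param freq numeric frequency grid in Hz, within `[0, fs/2]`.
#' @return numeric PSD values, same length as `freq`.
#' @export
ar_psd <- function(model, freq) {
  stopifnot(inherits(model, "lpc_model"))
  fs <- model$fs
  if (any(freq < 0) || any(freq > fs / 2))
    stop("frequency grid must lie within [0, fs/2] = [0, ", fs / 2, "]")
  Ts <- 1 / fs
  k <- seq_along(model$coeffs)
  denom <- vapply(freq, function(f)
    Mod(1 - sum(model$coeffs * exp(-2i * pi * f * k * Ts)))^2, numeric(1))
  model$residual * Ts / denom
}

## ---- streaming (expanding-window) estimator -------------------------------

#' Streaming LPC estimator
#'
#' Maintains exact running lag-product sums so the LPC fit on the full
#' prefix seen so far can be recomputed after every update at O(order)
#' cost per new sample, independent of the prefix length. No forgetting
#' factor: the window is cumulative, matching expanding-window analysis.
#'
#' `lpc_stream_init` creates the state, `lpc_stream_update` folds in new
#' samples, `lpc_stream_model` solves for the current model (equal to
#' [fit_lpc()] on the concatenation of everything seen).
#'
#' @param order model order.
#' @param fs sampling rate, Hz.
#' @return `lpc_stream_init`: state object of class `"lpc_stream"`.
#' @export
lpc_stream_init <- function(order = 1L, fs = 1000) {
  structure(list(order = as.integer(order), fs = fs,
                 s = numeric(order + 1L), count = 0L,
                 tail = numeric(0)),
            class = "lpc_stream")
}

#' @rdname lpc_stream_init
#' @param state an `"lpc_stream"` state.
#' @param samples numeric vector of new samples (may be empty).
#' @return `lpc_stream_update`: the updated state.
#' @export
lpc_stream_update <- function(state, samples) {
  stopifnot(inherits(state, "lpc_stream"))
  m <- length(samples)
  if (m == 0L) return(state)
  N <- state$order
  t0 <- length(state$tail)
  z <- c(state$tail, as.numeric(samples))
  for (l in 0:N) {
    lo <- max(t0 + 1L, l + 1L)
    hi <- t0 + m
    if (lo <= hi) {
      idx <- lo:hi
      state$s[l + 1L] <- state$s[l + 1L] + sum(z[idx] * z[idx - l])
    }
  }
  state$count <- state$count + m
  keep <- min(N, length(z))
  state$tail <- if (keep > 0L) z[(length(z) - keep + 1L):length(z)] else numeric(0)
  state
}

#' @rdname lpc_stream_init
#' @return `lpc_stream_model`: the `"lpc_model"` for the prefix seen so far.
#' @export
lpc_stream_model <- function(state) {
  stopifnot(inherits(state, "lpc_stream"))
  if (state$count <= state$order)
    stop("not enough samples streamed (", state$count,
         ") for order ", state$order)
  ac <- structure(list(lags = state$s / state$count, L = state$count,
                       estimator = "biased"),
                  class = "autocorr_set")
  ld <- levinson_durbin(ac, state$order)
  model <- structure(
    list(order = state$order, coeffs = ld$coeffs[[state$order]],
         residual = ld$residuals[state$order], reflection = ld$reflection,
         r0 = ld$r0, fs = state$fs,
         poles = NULL, pole_radius = NA_real_, dominant_freq_hz = NA_real_),
    class = "lpc_model")
  if (state$order == 2L) {
    p <- poles_of_order2(model$coeffs)
    model$poles <- p
    model$pole_radius <- Mod(p[1])
    model$dominant_freq_hz <- dominant_frequency(p, state$fs)
  }
  model
}

#' Expanding-window LPC coefficient trace
#'
#' Emulates real-time estimation: the first-order coefficient (and the
#' separation feature derived from it) is computed on the first `init_s`
#' seconds, then updated as the window expands in `step_s`-second
#' increments, using the streaming estimator so the whole trace costs one
#' pass over the series.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param init_s,step_s initial window and increment, seconds.
#' @param order model order (default 1).
#' @return data frame with `window_s`, `n_samples`, `a1` (first
#'   coefficient) and `feature` (the order-1 separation feature, `NA` for
#'   higher orders).
#' @export
lpc_trace <- function(x, fs, init_s = 1, step_s = 1, order = 1L) {
  sizes <- expanding_windows(x, fs, init_s, step_s)
  state <- lpc_stream_init(order, fs)
  prev <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    state <- lpc_stream_update(state, x[(prev + 1L):sizes[i]])
    prev <- sizes[i]
    model <- lpc_stream_model(state)
    out[[i]] <- data.frame(
      window_s = sizes[i] / fs, n_samples = sizes[i],
      a1 = model$coeffs[1],
      feature = if (order == 1L) separation_feature(model) else NA_real_)
  }
  do.call(rbind, out)
}
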