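fs <- 1000

test_that("biased autocorrelation matches hand evaluation and asymptotics", {
  ac <- autocorr(c(1, 2, 3), 2)
  expect_equal(ac$lags, c(14, 8, 3) / 3)
  expect_equal(ac$L, 3L)
  expect_equal(ac$estimator, "biased")
  expect_error(autocorr(1:3, 3), "maxlag")

  set.seed(31)
  w <- rnorm(50000)
  acw <- autocorr(w, 1)
  expect_lt(abs(acw$lags[2] / acw$lags[1]), 3 / sqrt(50000))

  # sinusoid: r(l) proportional to cos(2 pi f0 l Ts) at small lags
  f0 <- 25
  x <- sin(2 * pi * f0 * seq_len(20000) / fs)
  acs <- autocorr(x, 40)
  expect_equal(acs$lags / acs$lags[1], cos(2 * pi * f0 * (0:40) / fs),
               tolerance = 0.02)
  # biased estimator keeps |r(l)| <= r(0)
  expect_true(all(abs(acs$lags) <= acs$lags[1] + 1e-12))
})

test_that("Yule-Walker direct solve matches closed forms", {
  r <- c(14, 8, 3) / 3
  expect_equal(yule_walker(r, 1), 4 / 7)
  expect_equal(yule_walker(r, 2), c(2 / 3, -1 / 6))
  # independent 2x2 inversion oracle
  expect_equal(yule_walker(r, 2),
               as.numeric(solve(matrix(c(r[1], r[2], r[2], r[1]), 2),
                                r[2:3])))
  expect_equal(yule_walker(c(1, 0, 0, 0), 3), numeric(3))  # white noise
  # perfectly predictable series: lag-independent autocorrelation makes
  # the Toeplitz system singular
  expect_error(yule_walker(c(1, 1, 1), 2), "singular")
})

test_that("Levinson-Durbin equals direct inversion and obeys residual laws", {
  r <- c(14, 8, 3) / 3
  ld <- levinson_durbin(r, 2)
  expect_equal(ld$coeffs[[2]], c(2 / 3, -1 / 6), tolerance = 1e-12)
  expect_equal(ld$coeffs[[1]], 4 / 7)
  expect_equal(ld$residuals[1], r[1] * (1 - (4 / 7)^2))  # J1 closed form
  expect_equal(ld$residuals,
               r[1] * cumprod(1 - ld$reflection^2))

  ldw <- levinson_durbin(c(1, 0, 0, 0), 3)
  expect_equal(ldw$reflection, numeric(3))
  expect_equal(ldw$residuals, rep(1, 3))  # J_m = r(0) for white noise

  set.seed(32)
  for (rep in 1:50) {
    r <- random_autocorr(200, 6)
    ord <- sample(1:6, 1)
    ld <- levinson_durbin(r, ord)
    for (m in seq_len(ord)) {
      direct <- yule_walker(r, m)
      expect_equal(ld$coeffs[[m]], direct, tolerance = 1e-10)
    }
    expect_true(all(diff(ld$residuals) <= 1e-12))   # J non-increasing
    expect_lte(ld$residuals[ord], r[1] + 1e-12)     # J <= r(0)
  }
  expect_error(levinson_durbin(c(0, 0), 1), "positive")
})

test_that("fit_lpc recovers known AR(1) and AR(2) parameters", {
  x1 <- sim_ar(0.9, 60000, seed = 33)
  m1 <- fit_lpc(x1, fs, 1)
  expect_lt(abs(m1$coeffs - 0.9), 0.01)
  expect_lte(m1$residual, m1$r0)

  set.seed(34)
  mw <- fit_lpc(rnorm(60000), fs, 2)
  expect_lt(max(abs(mw$coeffs)), 0.02)
  expect_equal(mw$residual, mw$r0, tolerance = 0.01)

  a <- ar2_coeffs(0.95, 14, fs)  # (1.892654, -0.9025)
  expect_equal(a, c(1.892654, -0.9025), tolerance = 1e-6)
  x2 <- sim_ar(a, 60000, seed = 35)
  m2 <- fit_lpc(x2, fs, 2)
  expect_lt(max(abs(m2$coeffs - a)), 0.01)
  expect_lt(abs(m2$dominant_freq_hz - 14), 0.5)
})

test_that("second-order poles follow the quadratic closed form", {
  p <- poles_of_order2(c(2 / 3, -1 / 6))
  expect_equal(sort(Re(p)), rep(1 / 3, 2))
  expect_equal(sort(Im(p)), c(-1, 1) * sqrt(2) / 6, tolerance = 1e-12)
  expect_equal(Mod(p), rep(sqrt(1 / 6), 2))

  pr <- poles_of_order2(c(0.5, 0.24))
  expect_equal(sort(Re(pr)), c(-0.3, 0.8))
  expect_equal(Im(pr), c(0, 0))

  # a = (2 A cos t, -A^2) -> poles A e^{+-it}, exactly
  A <- 0.93; th <- 0.4
  pc <- poles_of_order2(c(2 * A * cos(th), -A^2))
  expect_equal(Mod(pc), c(A, A), tolerance = 1e-12)
  expect_equal(sort(Arg(pc)), c(-th, th), tolerance = 1e-12)
})

test_that("dominant frequency reads the pole phase; real poles carry none", {
  A <- 0.95; th <- 2 * pi * 14 / fs
  p <- poles_of_order2(c(2 * A * cos(th), -A^2))
  expect_equal(dominant_frequency(p, fs), 14)
  expect_true(is.na(dominant_frequency(poles_of_order2(c(0.5, 0.24)), fs)))
  # coincident poles on the negative real axis: the Nyquist limit
  expect_equal(dominant_frequency(complex(real = c(-A, -A)), fs), fs / 2)
})

test_that("the separation feature scales (1 - a1) and tracks bandwidth", {
  expect_equal(separation_feature(0.99714), 2.86)
  m <- fit_lpc(sim_ar(0.99714, 5000, seed = 36), fs, 1)
  expect_equal(separation_feature(m), (1 - m$coeffs) * 1e3)
  expect_equal(separation_feature(1), 0)
  expect_error(separation_feature(fit_lpc(rnorm(1000), fs, 2)), "order-1")

  # broader bandwidth (smaller pole radius) -> faster autocorrelation
  # decay -> larger feature
  narrow <- sim_ar(ar2_coeffs(0.995, 13, fs), 60000, seed = 37)
  broad <- sim_ar(ar2_coeffs(0.95, 13, fs), 60000, seed = 38)
  expect_gt(separation_feature(fit_lpc(broad, fs, 1)),
            separation_feature(fit_lpc(narrow, fs, 1)))
})

test_that("the AR-model PSD has the expected shape", {
  grid <- seq(0.5, 499.5, by = 0.5)
  set.seed(39)
  white <- fit_lpc(rnorm(20000), fs, 1)
  white$coeffs <- 0  # exactly flat reference
  s <- ar_psd(white, grid)
  expect_equal(s, rep(white$residual / fs, length(grid)))

  ar1 <- fit_lpc(sim_ar(0.9, 20000, seed = 40), fs, 1)
  s1 <- ar_psd(ar1, grid)
  expect_true(all(diff(s1) < 0))  # monotone decreasing for a1 > 0

  # near-unit pole radius: spectral maximum sits at the pole frequency
  ar2 <- fit_lpc(sim_ar(ar2_coeffs(0.99, 14, fs), 60000, seed = 41), fs, 2)
  s2 <- ar_psd(ar2, grid)
  expect_lt(abs(grid[which.max(s2)] - 14), 0.5)
  # broad pole (A = 0.95): the peak shifts off the pole frequency but
  # matches the closed-form argmax of the exact spectrum. Feed the
  # process's exact autocorrelation (r1 = a1 r0 / (1 - a2),
  # r2 = a1 r1 + a2 r0) through the fit so no sampling noise enters.
  a_true <- ar2_coeffs(0.95, 14, fs)
  r1 <- a_true[1] / (1 - a_true[2])
  r_exact <- c(1, r1, a_true[1] * r1 + a_true[2])
  ld <- levinson_durbin(r_exact, 2)
  expect_equal(ld$coeffs[[2]], a_true, tolerance = 1e-12)
  model <- structure(list(order = 2L, coeffs = ld$coeffs[[2]],
                          residual = ld$residuals[2], r0 = 1, fs = fs),
                     class = "lpc_model")
  exact <- 1 / Mod(1 - a_true[1] * exp(-2i * pi * grid / fs) -
                     a_true[2] * exp(-4i * pi * grid / fs))^2
  expect_equal(grid[which.max(ar_psd(model, grid))],
               grid[which.max(exact)])
  expect_gt(abs(grid[which.max(exact)] - 14), 2)  # genuinely shifted
  expect_error(ar_psd(ar1, c(10, 600)), "Nyquist|fs/2")
})

test_that("streaming updates reproduce batch fits exactly", {
  x <- sim_ar(ar2_coeffs(0.97, 12, fs), 10000, seed = 42)
  state <- lpc_stream_init(2, fs)
  for (k in seq_len(10)) {
    state <- lpc_stream_update(state, x[((k - 1) * 1000 + 1):(k * 1000)])
    batch <- fit_lpc(x[1:(k * 1000)], fs, 2)
    expect_equal(lpc_stream_model(state)$coeffs, batch$coeffs,
                 tolerance = 1e-9)
    expect_equal(lpc_stream_model(state)$residual, batch$residual,
                 tolerance = 1e-9)
  }
  # empty update leaves the state untouched
  expect_identical(lpc_stream_update(state, numeric(0)), state)
  # ragged chunk sizes agree too
  s2 <- lpc_stream_init(2, fs)
  cuts <- c(0, 7, 8, 150, 151, 4999, 10000)
  for (i in 2:length(cuts))
    s2 <- lpc_stream_update(s2, x[(cuts[i - 1] + 1):cuts[i]])
  expect_equal(lpc_stream_model(s2)$coeffs, fit_lpc(x, fs, 2)$coeffs,
               tolerance = 1e-9)
})

test_that("expanding-window traces separate two conditions within a minute", {
  dur <- 120
  sal <- sim_ar(ar2_coeffs(0.995, 12.2, fs), dur * fs, seed = 43)
  lev <- sim_ar(ar2_coeffs(0.985, 14.2, fs), dur * fs, seed = 44)
  tr_s <- lpc_trace(sal, fs)
  tr_l <- lpc_trace(lev, fs)
  expect_equal(nrow(tr_s), dur)
  # batch-fit oracle at an arbitrary prefix
  k <- 37
  expect_equal(tr_s$a1[k], fit_lpc(sal[1:(k * fs)], fs, 1)$coeffs,
               tolerance = 1e-9)
  # traces separate and stabilize from 60 s onward
  late <- 60:dur
  expect_true(all(tr_l$feature[late] > tr_s$feature[late]))
  gap <- mean(tr_l$feature[late]) - mean(tr_s$feature[late])
  expect_lt(max(abs(diff(tr_s$feature[late]))), gap / 4)
  expect_lt(max(abs(diff(tr_l$feature[late]))), gap / 4)
})
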