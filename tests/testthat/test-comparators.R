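fs <- 1000

test_that("Welch PSD is flat for white noise and conserves power", {
  set.seed(51)
  x <- normalize_unit_power(rnorm(60 * fs))
  p <- welch_psd(x, fs)
  df <- p$freq[2] - p$freq[1]
  expect_equal(df, 0.5)
  # Parseval: integral over (0, fs/2) recovers the unit power
  expect_gt(sum(p$psd) * df, 0.95)
  expect_lt(sum(p$psd) * df, 1.05)
  # flat at the 2/fs one-sided level: check 10 Hz block averages
  sel <- p$freq > 0 & p$freq < fs / 2
  blocks <- tapply(p$psd[sel], (p$freq[sel] - 0.01) %/% 10, mean)
  expect_true(all(abs(blocks / (2 / fs) - 1) < 0.2))

  tone <- sin(2 * pi * 20 * seq_len(60 * fs) / fs)
  pt <- welch_psd(tone, fs)
  expect_equal(pt$freq[which.max(pt$psd)], 20)
  expect_error(welch_psd(rnorm(100), fs, window_s = 2), "longer than series")
})

test_that("beta power is the in-band fraction and is gain-invariant", {
  t <- seq_len(60 * fs) / fs
  expect_gt(beta_power(sin(2 * pi * 20 * t), fs), 0.99)
  expect_lt(beta_power(sin(2 * pi * 5 * t), fs), 0.01)
  set.seed(52)
  w <- rnorm(60 * fs)
  bw <- beta_power(w, fs)
  expect_gt(bw, 0.036 - 0.005)   # 18 Hz band / 500 Hz bandwidth
  expect_lt(bw, 0.036 + 0.005)
  expect_equal(beta_power(w * 1000, fs), bw)
  expect_gte(bw, 0); expect_lte(bw, 1)
})

test_that("the modulation index separates coupled from uncoupled signals", {
  set.seed(53)
  w <- rnorm(60 * fs)
  expect_lt(pac_mi(w, fs, c(5, 7), c(50, 200)), 0.01)

  s <- gen_pac_signal(fs, 60, f_phase = 6, f_amp = 80, depth = 0.8,
                      seed = 54)
  mi <- pac_mi(s, fs, c(5, 7), c(50, 200))
  expect_gt(mi, 0.01)
  expect_lte(mi, 1)
  # amplitude rescaling leaves the index unchanged
  expect_equal(pac_mi(s * 250, fs, c(5, 7), c(50, 200)), mi,
               tolerance = 1e-10)

  # surrogate null: shuffling the phase series against the envelope
  # destroys the phase-amplitude dependence
  xp <- lfplpc:::pac_band_filter(s, fs, band_spec("theta", 5, 7))
  xa <- lfplpc:::pac_band_filter(s, fs, band_spec("gamma", 50, 200))
  phase <- Arg(lfplpc:::analytic_signal(xp))
  amp <- Mod(lfplpc:::analytic_signal(xa))
  set.seed(55)
  null_mi <- replicate(20,
    lfplpc:::mi_from_phase_amp(sample(phase), amp, 18L))
  expect_gt(mi, 5 * mean(null_mi))

  # envelope concentrated in a single phase bin attains the KL bound
  ph <- rep(seq(-pi + 0.01, pi - 0.01, length.out = 18 * 50), 4)
  a1bin <- as.numeric(ph > -pi + 0.01 & ph < -pi + 2 * pi / 18)
  expect_equal(lfplpc:::mi_from_phase_amp(ph, a1bin, 18L), 1)

  expect_error(pac_mi(w, fs, c(5, 7), c(400, 600)), "Nyquist")
  expect_error(pac_mi(w[1:1000], fs, c(5, 7), c(50, 200)), "too short")
  expect_warning(pac_mi(sin(2 * pi * 6 * seq_len(30 * fs) / fs), fs,
                        c(5, 7), c(200, 350)), "below")
})

test_that("the PAC grid has 36 cells and localizes constructed coupling", {
  set.seed(56)
  g <- pac_grid(rnorm(60 * fs), fs)[[1]]
  expect_s3_class(g, "pac_grid_result")
  expect_equal(dim(g$mi), c(6, 6))
  expect_equal(length(g$mi), 36)
  expect_true(all(g$mi >= 0 & g$mi <= 1))
  expect_true(all(g$mi < 0.01))  # white noise: no coupling anywhere

  s <- gen_pac_signal(fs, 60, f_phase = 6, f_amp = 45, depth = 0.8,
                      seed = 57)
  gc <- pac_grid(s, fs)[[1]]
  peak <- which(gc$mi == max(gc$mi), arr.ind = TRUE)
  expect_equal(rownames(gc$mi)[peak[1]], "theta")
  expect_equal(colnames(gc$mi)[peak[2]], "gamma")
})

test_that("the CCA composite needs n > p, finds the informative feature", {
  set.seed(58)
  expect_error(cca_composite(matrix(runif(30 * 36), 30), rep(c("a", "b"), 15)),
               "greater than the number of PAC measurements")

  n <- 104; p <- 36
  labels <- rep(c("saline", "levodopa"), each = n / 2)
  X <- matrix(runif(n * p, 0, 0.01), n, p)
  X[labels == "levodopa", 7] <- X[labels == "levodopa", 7] + 0.05
  cc <- cca_composite(X, labels)
  expect_equal(which.max(abs(cc$weights)), 7L)
  # composite separates the conditions completely, oriented upward for
  # the second factor level ("saline" here, alphabetically second)
  expect_gt(min(cc$composite[labels == cc$levels[2]]),
            max(cc$composite[labels == cc$levels[1]]))

  # permuted labels: observed canonical correlation sits inside its own
  # permutation null
  y_perm <- sample(labels)
  Xnull <- matrix(runif(n * p), n, p)
  obs <- cca_composite(Xnull, y_perm)$cor
  null <- replicate(200, cca_composite(Xnull, sample(y_perm))$cor)
  expect_lte(obs, quantile(null, 0.99))

  # rank-deficient feature block is refused
  Xdef <- cbind(X[, 1:35], X[, 35])
  expect_error(cca_composite(Xdef, labels), "rank-deficient")
})
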