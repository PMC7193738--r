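# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# two-sided exact rank-sum p-value by brute-force enumeration of all
# C(n1+n2, n1) rank assignments (no ties assumed)
brute_force_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# AR(2) coefficients for a conjugate pole pair at radius A, frequency f0
ar2_coeffs <- function(A, f0, fs) c(2 * A * cos(2 * pi * f0 / fs), -A^2)

# direct AR simulation without the package generator
sim_ar <- function(coeffs, n, burn = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n + burn)
  as.numeric(stats::filter(e, coeffs, method = "recursive"))[(burn + 1):(burn + n)]
}

# biased autocorrelation of a fresh random series: guaranteed numerically
# positive definite input for solver tests
random_autocorr <- function(len, maxlag) {
  x <- rnorm(len)
  vapply(0:maxlag, function(l)
    sum(x[(l + 1):len] * x[1:(len - l)]) / len, numeric(1))
}
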