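---
title: "Low-order linear prediction as an LFP brain-state biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-order linear prediction as an LFP brain-state biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfplpc)
```

## The problem

Adaptive deep-brain stimulation (aDBS) needs a trigger: a scalar statistic
of ongoing neural activity, cheap enough to update every few milliseconds
on implanted hardware, that tracks the pathological state it is supposed
to correct. The conventional choice is beta-band (12-30 Hz) power of a
basal-ganglia local field potential (LFP), which requires a
Fourier-analysis window and captures only one slice of the spectrum.

`lfplpc` implements an alternative: fit a first- or second-order
autoregressive (AR) model — linear predictive coding, LPC — to the LFP and
use the fitted parameters as the state readout. An order-1 model is a
single coefficient; it can be updated sample-by-sample at constant cost,
and it summarizes the *overall* spectral shape (how fast the signal
decorrelates) rather than the power in one band. In dopamine-depleted
rodents, a levodopa challenge broadens the striatal LFP spectrum and
shifts its dominant frequency upward; both effects move the lag-one
correlation, so a single LPC coefficient separates the treated and
untreated states.

## The model

For a series $x(0),\dots,x(L-1)$ the order-$N$ predictor is
$\hat x(n) = \sum_{k=1}^{N} a_k x(n-k)$, with coefficients chosen to
minimize the mean-square error $J = E[|x(n)-\hat x(n)|^2]$. The optimum
solves the Yule-Walker system $R_N \, a = r_N$, where $R_N$ is the
Toeplitz matrix of autocorrelations at lags $0..N-1$ and $r_N$ stacks
lags $1..N$. Expectations are replaced by the *biased* time average
$r(l) = \frac1L \sum_{n=l}^{L-1} x(n)x(n-l)$ (`autocorr()`): dividing by
$L$ rather than $L-l$ guarantees a positive-semidefinite $R_N$, so the
Levinson-Durbin recursion (`levinson_durbin()`) is always well posed and
produces every lower order and residual $J_m = r(0)\prod_i(1-k_i^2)$ on
the way. `yule_walker()` keeps the direct Toeplitz solve as an
independent route; the two agree to $10^{-10}$ relative error and the
test suite holds them against each other.

For order 2 the characteristic roots of $z^2 - a_1 z - a_2$ are the model
poles. A conjugate pair $A e^{\pm i 2\pi f_0 T_s}$ encodes a spectral
peak: the radius $A$ sets the bandwidth (narrower as $A \to 1$) and the
phase sets the **dominant frequency** $f_0 = |\arg p| \, f_s / 2\pi$
(`dominant_frequency()`). Real poles mean no oscillatory component and
the function returns `NA`.

### The separation feature and its sign

The classification scalar is $\delta = (1 - a_1)\times 10^3$
(`separation_feature()`). Under the predictor convention above, strongly
low-pass signals give $a_1$ just below $+1$, so $\delta$ is small and
positive, and broader-band signals (faster decorrelation at lag one)
give larger $\delta$. Conventions in the literature differ: with a
prediction-*error*-filter convention the same quantity appears as
$(1 + a_1)\times 10^3$ with $a_1 \approx -1$. The two are numerically
identical; this package states and uses the predictor form throughout.

### Model-implied spectrum

`ar_psd()` evaluates $S(f) = J\,T_s / |1 - \sum_k a_k e^{-i2\pi f k
T_s}|^2$. One caveat worth knowing: the argmax of an AR(2) spectrum
coincides with the pole frequency only in the narrowband limit. At
$A = 0.95$, $f_0 = 14$ Hz, $f_s = 1$ kHz the exact spectral peak sits at
11.4 Hz, 2.6 Hz below the pole frequency; at $A = 0.99$ the gap shrinks
to 0.1 Hz. The tests assert the closed-form peak location, not the naive
peak-equals-pole identity.

## Preprocessing chain

Per channel: zero-phase FIR bandpass, then unit-power normalization
($x/\sqrt{P}$, $P = \frac1L\sum x^2$); then the channels are averaged
into one series (`preprocess_recording()`). Normalizing before averaging
removes each electrode's gain, making the chain invariant to per-channel
rescaling — a tested property.

The filter is a linear-phase windowed-sinc FIR (Hamming window),
passband 2.5-50 Hz, order $\approx 3.3 f_s$ (3300 at 1 kHz), giving a
~1 Hz transition and >40 dB attenuation at DC and above ~55 Hz. Zero
phase comes from removing the symmetric filter's known group delay after
a single forward pass — not from forward-backward filtering, which would
square the magnitude response. Edges are implicitly zero-padded; the
first and last ~1.65 s of a session are therefore attenuated. The
specific order/window pair is this package's documented choice; only the
band and the zero-phase requirement are externally fixed.

Normalization operates on whatever series is passed — in the standard
chain, the filtered full session before segmentation. Since the order-1
feature is the ratio $r(1)/r(0)$, it is scale-invariant anyway; the
normalization matters for the averaging step and for power-based
comparators.

Segmentation (`segment()`) uses non-overlapping, left-aligned epochs
from $t=0$, discarding the trailing remainder: a 40-min session at 3-min
epochs gives exactly 13 epochs with 60 s unused. Sample counts round
half-away-from-zero so they are platform-stable. Expanding windows
(`expanding_windows()`, `lpc_trace()`) start at 1 s and grow in 1-s
increments; the streaming estimator (`lpc_stream_*`) keeps exact running
lag sums so each update costs $O(N)$ per sample and reproduces the batch
fit on the full prefix to $10^{-9}$ — there is no forgetting factor, by
design, because the expanding window is cumulative.

## Comparator biomarkers

* **Beta power** (`beta_power()`): fraction of (0, $f_s/2$) Welch-PSD
  power in 12-30 Hz. Welch parameters (unstated in the trigger
  literature at this granularity) are 2-s Hamming segments with 50%
  overlap: 0.5 Hz resolution, ~90 averages on a 3-min epoch. The
  estimator conserves power to within a few percent (Parseval, tested).
* **PAC modulation index** (`pac_mi()`): Kullback-Leibler index on 18
  phase bins of 20 degrees (the de-facto standard bin count). Phase and
  envelope come from FFT analytic signals of zero-phase FIR band
  isolates whose order spans at least 3 cycles of the band's low edge.
  Two named pairings are provided: beta phase 13-30 Hz with gamma
  amplitude 50-200 Hz, and low-beta phase 12-30 Hz with HFO amplitude
  200-350 Hz. When the amplitude band holds less than $10^{-5}$ of the
  signal power (e.g. HFO on data low-passed at 200 Hz) the function
  warns that the index reflects noise rather than failing.
* **PAC grid + CCA composite** (`pac_grid()`, `cca_composite()`): all
  6 x 6 = 36 modulation indices over the 3-60 Hz sub-bands (delta 3-4,
  theta 5-7, alpha 8-11, low beta 12-19, high beta 20-30, gamma
  31-60 Hz), projected onto the first canonical direction against the
  condition indicator. Two "low beta" definitions circulate (12-19 Hz in
  the sub-band list, 12-30 Hz in the HFO pairing); both are exposed as
  named bands, each used where its source uses it. The composite
  requires more signals than features (104 epochs > 36 indices at 3-min
  segmentation) and is fitted on the pooled dataset — a documented
  limitation of the approach, since the weights are data-dependent.

In the end-to-end comparison the LPC features run on the full 2.5-50 Hz
chain, while beta power and PAC run on the normalized channel average
*without* that bandpass: their amplitude bands extend to 350 Hz and
would otherwise be emptied by the analysis filter itself.

## Separation statistics

`midpoint_threshold()` orients the two groups by median (tie-broken by
mean), puts the threshold halfway between the upper group's minimum and
the lower group's maximum, and reports the margin; a positive margin is
complete separation. `classify()` sends values at or above the threshold
to the upper condition (ties go up). The threshold is fitted on pooled
epochs across subjects, matching the pooled 52-per-condition design.

`ranksum_test()` uses exact enumeration when both groups have at most 10
observations and no ties, otherwise the normal approximation with
continuity correction and midranks. This branch rule matters: fully
separated 4 vs 4 groups give exactly $p = 2/70 = 0.0286$, and fully
separated 52 vs 52 groups give $p = 1.54\times10^{-18}$. For two groups
the Kruskal-Wallis $H$ equals the squared uncorrected rank-sum $z$, so
its p-value ($0.0209$, $1.5\times10^{-18}$ on the same inputs) differs
from the rank-sum one only by the continuity correction — both
identities are tested. No multiple-testing correction is applied, by
design: the comparison report is descriptive.

## The synthetic study

Real striatal recordings behind this design are not redistributable, so
the simulator (`synthlfp` functions) defines the study conditions the
package is validated on: 4 subjects per condition, 40-min, 1 kHz,
4-channel sessions. Each session is one shared AR(2) source — pole
radius $A$, dominant frequency $f_0$, unit-variance Gaussian
innovations, burn-in $10/(1-A)$ samples — plus independent per-channel
Gaussian noise at 10 dB SNR. The two conditions are
**saline-like** ($A = 0.995$, $f_0 = 12.2$ Hz: narrow, slow) and
**levodopa-like** ($A = 0.985$, $f_0 = 14.2$ Hz: broader, faster),
encoding the observation that levodopa broadens the spectrum and raises
the dominant frequency, with $f_0$ values inside the reported 11.7-12.8
and 13.8-14.7 Hz ranges. The radii are calibration choices fixed once;
10 dB channel noise is a realistic electrode-noise level for striatal
microwire arrays. Seeds derive from a master seed by a fixed counter
scheme, so any subset of sessions is reproducible in any order.

What the simulator deliberately does **not** model: nonstationarity
within a session (drug wash-in/wash-out), movement artifacts, 1/f
background mixtures, cross-frequency coupling in the LFP itself (coupled
signals are generated separately by `gen_pac_signal()` for PAC
validation), and dyskinesia states. Passing tests therefore demonstrate
that the pipeline recovers and separates the *encoded* spectral
differences end-to-end — not that real LFPs satisfy an AR(2) model.

## Problem sizes and numerical choices in the tests

* Parameter recovery uses $L = 60{,}000$ (1 min at 1 kHz): AR(1)
  coefficients land within 3 asymptotic standard deviations
  ($\sqrt{(1-a^2)/L}$) in over 99% of 500 replicates. For AR(2)
  dominant-frequency recovery the same $L$ gives errors well under
  0.5 Hz at the study radii ($A \ge 0.985$), but at broad poles the
  estimate is inherently noisier: at $A = 0.9$, $f_0 = 10$ Hz its
  standard deviation is ~0.9 Hz (identical in `stats::ar`, which serves
  as the cross-check), so a 0.5-Hz criterion cannot be met there by any
  Yule-Walker estimator at this $L$. The suite states the strict
  property and records the measured rate rather than relaxing it.
* The null-calibration study (the healthy-control analogue: both groups
  generated with identical parameters) runs 1000 replicates of 13 vs 13
  features. Each feature comes from an *independent* 10-s signal passed
  through the full chain. Ten-second signals keep the run to a couple of
  minutes; independence per feature is essential at that length because
  the 3.3-s analysis filter would otherwise correlate adjacent short
  epochs cut from one session (at the study's 3-min epochs the overlap
  is a negligible 1.8%). Measured rejection at $\alpha = 0.05$ sits at
  the nominal rate.
* Near-singular Yule-Walker systems (reciprocal condition below
  $10^{-12}$) are refused with a descriptive error. The threshold is
  deliberately tiny: legitimate narrowband fits at $A = 0.995$ already
  produce condition numbers near $10^{4}$.
* CSV round-trips write 9 significant digits, enough to reproduce the
  unit-power feature scale exactly for practical purposes.

## A worked example

```{r example, eval = FALSE}
specs <- condition_pair_specs(n_subjects = 4, seed = 1)
tab <- do.call(rbind, lapply(specs, function(s) {
  rec <- gen_session(s$spec, s$subject_id, s$condition)
  extract_features(preprocess_recording(rec), "lpc1", epoch_min = 3)
}))
sep <- midpoint_threshold(tab$value[tab$condition == "saline"],
                          tab$value[tab$condition == "levodopa"],
                          c("saline", "levodopa"))
sep
#> <separation_result> threshold 3.49123, margin 0.969646 (complete separation)
#>   upper condition: levodopa; rank-sum p = 1.54e-18, Kruskal-Wallis p = 1.5e-18
```

(Generating the eight 40-minute sessions takes a few minutes; the chunk
is not evaluated when the vignette is built.)

## Known limitations

* An order-1 or order-2 AR model is a deliberately coarse spectral
  summary; signals whose conditions differ only in features invisible to
  the first two autocorrelation lags will not separate.
* The midpoint threshold uses extremes (min/max), so a single outlier
  epoch moves it; the margin is reported precisely so that fragility is
  visible.
* The CCA composite's weights are refitted per dataset and do not
  transfer; the package exposes them but draws no generality claims.
* Zero-phase filtering is non-causal; the streaming estimator is causal
  but consumes the *filtered* series in this package's pipeline. A fully
  causal deployment would substitute a causal filter and accept the
  group delay.
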