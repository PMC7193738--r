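Package: lfplpc
Title: Linear Predictive Coding Features for Separating Brain States in
    Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits low-order autoregressive (linear predictive coding, LPC)
    models to local field potential (LFP) recordings and uses the fitted
    coefficients, poles and dominant frequencies as lightweight biomarkers
    for separating pharmacological brain states, as in adaptive
    deep-brain-stimulation trigger design.  Includes the full preprocessing
    chain (zero-phase FIR bandpass, unit-power normalisation, channel
    averaging, epoch segmentation, expanding windows), a constant-cost
    streaming LPC estimator, comparator biomarkers (beta-band power and
    Kullback-Leibler phase-amplitude-coupling modulation indices, singly and
    as a 36-cell grid with a canonical-correlation composite), nonparametric
    separation statistics with a midpoint threshold classifier, and a
    reproducible synthetic multi-channel LFP simulator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
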