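Package: stopsig
Title: Simulation and Analysis of the Stop-Signal Anticipation Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing the stop-signal
    anticipation task, a paradigm for studying reactive and proactive
    response inhibition. Builds pseudorandomised trial sequences with cued
    stop-signal probability levels, runs per-level 1-up-1-down staircases on
    the stop-signal onset time, simulates per-trial behaviour from an
    independent horse-race model with proactive slowing, and estimates the
    stop-signal reaction time (SSRT) by the integration method together with
    ZRFT-normalised inhibition functions and cumulative Weibull fits. A
    forward model generates region-by-scan BOLD time series with planted
    condition effects so that the included event-related GLM (parametric
    modulators, discrete-cosine high-pass, AR(1) prewhitening) and
    psychophysiological-interaction (PPI) analysis with hemodynamic
    deconvolution can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
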