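Package: attnfc
Title: Attention-Network Functional Connectivity and Cross-Task Training Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for multi-session attention-training
    studies with resting-state fMRI readouts. Generates synthetic cohorts (ROI BOLD
    time series with known connectivity structure, head-motion traces, psychophysical
    observers), implements censoring-aware time-series preprocessing (nuisance
    regression, detrending, motion scrubbing with least-squares spectral interpolation,
    zero-phase band-pass filtering, retention rules), seed-based Fisher-z functional
    connectivity of the dorsal-ventral attention network against a default-mode
    control network, an adaptive 3-down-1-up staircase with point-of-subjective-equality
    threshold estimation, the repeated-measures ANOVA battery with sphericity and
    homogeneity corrections, and a finite-impulse-response deconvolution GLM with
    false-discovery-rate thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
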