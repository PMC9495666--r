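Package: adiagait
Title: Adiabatic-Invariant Analysis of Walking Dynamics and Stride-Interval Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the global stability of human walking through the
    adiabatic invariant of vertical center-of-mass (COM) motion, alongside the
    local variability, predictability and complexity of stride-interval time
    series. Provides a stochastic frequency-modulated harmonic-oscillator
    simulator of COM motion and a fractional-Gaussian-noise stride generator;
    marker-based COM kinematics (adaptive zero-phase Butterworth filtering,
    cubic-spline upsampling, finite-difference velocities); gait-cycle
    segmentation with per-cycle frequency, mean kinetic energy, the adiabatic
    invariant and phase-space attractor averaging; stride-interval metrics
    (coefficient of variation, detrended fluctuation analysis Hurst exponent,
    Minkowski box-counting dimension, sample entropy); and a statistical layer
    with normality-gated paired comparisons, zero-intercept regression and
    ANCOVA, and dynamic time warping distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
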