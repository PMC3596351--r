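Package: locodyn
Title: Intermittent Locomotor Dynamics: Wavelet Rhythms, Bout-Duration
    Laws, and Priority-Queue Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of intermittent locomotor activity time series of the
    kind recorded by piezoelectric actigraphy in rodents. Converts raw sensor
    signals into detrended local-variance activity series, quantifies circadian
    and ultradian rhythmicity with a Morlet continuous wavelet transform
    (normalized spectrum, dominant-peak circadian period, circadian/ultradian
    band areas and their ratio), extracts resting and active bout durations by
    threshold crossing and fits mean-rescaled cumulative distributions with
    power-law and stretched-exponential forms via orthogonal distance
    regression, simulates the stochastic priority-queuing model of bursty
    behavior, and generates synthetic locomotor recordings with prescribed
    rhythm and bout-duration statistics for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    multcomp,
    withr
Config/testthat/edition: 3
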