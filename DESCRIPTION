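Package: hopfcochlea
Title: Critical Hopf-Oscillator Simulation and Compression Statistics for
    Cochlear Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates tone-evoked responses of cochlear segments modeled as
    forced Hopf oscillators poised near criticality, with a passive linear
    pathway, repeated presentations and measurement noise, and implements the
    statistical pipeline used to detect criticality signatures in such
    recordings: FFT phasor extraction with a Rayleigh phase-locking gate,
    local log-log compression slopes from overlapping triplets and
    quadruplets with standard-error filtering, per-segment minimum-slope
    cohort statistics, piecewise sensitivity fits with inflection-point
    alignment, and distortion-product level scaling contrasted against a
    saturating-transducer null. Includes zwuis multitone stimulus design with
    combination-tone collision checking.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
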