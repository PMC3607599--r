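Package: sporeflow
Title: Quantitative Analysis of Spore Germination and Outgrowth from
    Phase-Contrast Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of phase-contrast time-lapse image stacks of
    Bacillus spores: detection of phase-bright spores in the first frame,
    timing of germination from the bright-to-dark center-intensity drop
    (90%/10% drop-range crossings), colony contour and area tracking with
    censoring at colony or boundary contact, first-division and coat-burst
    detection, generation-time fitting from log2(area)-vs-time windows, fate
    classification of individual spores, and two-condition population
    statistics (F-test followed by the appropriate t-test). Includes a
    forward simulator of phase-contrast-like movies with per-spore ground
    truth, so every analysis stage can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
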