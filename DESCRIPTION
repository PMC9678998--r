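Package: presynquant
Title: Quantal and Kinetic Analysis of Presynaptic Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for presynaptic electrophysiology and
    functional imaging: detection and statistics of miniature postsynaptic
    currents, evoked-train quantal analysis with readily-releasable-pool
    (RRP) and release-probability estimation by cumulative-amplitude
    back-extrapolation, paired-pulse ratios, bi-/mono-exponential fitting of
    short-term depression and recovery, ratiometric Fura-2 calcium
    calibration via the Grynkiewicz equation, SyGCaMP basal/evoked
    normalization, and synaptopHluorin exo-/endocytosis kinetics. A
    synthetic-data generator produces every input with known ground truth so
    each estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
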