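Package: weakhar
Title: Weak-Label Human Activity Recognition from Smartphone Sensors
Version: 0.1.0
Authors@R:
    person("Federico", "Marchetti", email = "fmarchetti@example.org",
           role = c("aut", "cre"))
Description: Automatic weak labeling of free-living human activity from
    smartphone step counts and sparse GPS fixes. A fuzzy heuristic fuses
    step cadence (Gaussian memberships for walking and running) with
    GPS-derived ground speed (trapezoidal memberships) into
    probability-scored weak labels over five activity classes. The package
    also provides accelerometer feature extraction (1-s windows, 50%
    overlap, 18 time and frequency domain features), quality-aware class
    balancing by label probability, a weak-label-train / true-label-test
    cross-validation protocol with six classifier families implemented in
    base R, label-noise injection experiments, and a synthetic free-living
    trace generator so the full chain is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
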