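Package: o2deficit
Title: Accumulated Oxygen Deficit Estimation from Cycle-Ergometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating anaerobic energy release by the accumulated
    oxygen deficit (AOD) principle from cycle-ergometer measurements. Builds
    linear power to oxygen-demand relationships by nine computational methods
    (ordinary least squares on long or short bouts, stepwise protocols, forced
    common intercepts, gross- and net-efficiency anchors), extrapolates them to
    supramaximal exercise models, computes accumulated demand, uptake and
    deficit, and compares methods against a reference with paired statistics.
    Includes a synthetic-cohort generator that emulates the measurement
    structure of graded cycle-ergometry studies (slow-component drift,
    low-power non-linearities, cubic frequency dependence of loadless
    pedaling), so every estimator is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
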