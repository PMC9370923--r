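Package: gaitcog
Title: Temporal Gait Characteristics, Signal Complexity and Cognitive
    Prediction from Shank-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline linking wearable-sensor gait to cognition in
    midlife cohorts. Simulates shank motion signals for 20 m walking tasks
    with known ground-truth gait events, preprocesses recordings (trim,
    resample to 200 Hz, median + zero-phase Butterworth filtering), detects
    and labels toe-off, max-swing-velocity and heel-strike events, derives
    swing/stance/stride times with a two-standard-deviation turning-artifact
    rule, stride-time variability and a multiscale-entropy complexity index,
    and compares multivariable linear regression against a descending-width
    sigmoid neural network for predicting Montreal Cognitive Assessment
    scores under repeated 80/20 hold-out validation with mean absolute
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr,
    optparse
Config/testthat/edition: 3
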