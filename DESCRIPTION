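Package: gazeflow
Title: Fixation, Entropy and Markov Transition Analysis of Driver Gaze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing where drivers look and how their gaze moves
    between areas of interest (AOIs). Implements velocity-threshold (I-VT)
    fixation detection with sub-75 ms glance merging, nine-region AOI coding,
    a duration-weighted fixation entropy rate for quantifying gaze
    randomness, and first-order Markov analysis of AOI transitions
    (one-step and empirical two-step matrices, stationary distributions,
    region merging, and transition-change proportions). A seeded synthetic
    gaze generator produces AOI label sequences from configurable Markov
    chains and raw gaze-point streams with fixation clusters, saccades and
    blink gaps, so the full pipeline can be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    MASS,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
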