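Package: gazeprime
Title: Saccade Detection and Reaction-Time Analysis for Cueing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for high-speed (300 Hz) eye-tracking
    experiments on saccadic priming: builds balanced within-subject trial
    schedules for a precueing design, simulates gaze traces with
    main-sequence saccade kinematics and known ground truth, preprocesses
    raw gaze samples (zero-phase low-pass filtering, blink masking),
    detects saccades with a dual-threshold velocity algorithm, extracts
    saccadic reaction times and landing errors, and runs repeated-measures
    ANOVA with Greenhouse-Geisser correction and generalized eta squared.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    signal,
    jsonlite,
    generics,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
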