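Package: chemodrift
Title: Run-and-Tumble Simulation and Trajectory Analysis of
    Adaptation-Deficient Bacterial Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based run-and-tumble simulation of Escherichia coli
    populations in linear attractant gradients, with homogeneous and
    heterogeneous (phenotypically diverse) tumbling-bias response models and
    optional hour-scale adaptation; trajectory analysis of 2-D tracking data
    (swimmer filtering, sliding-window velocity fits, ballisticity-based
    run/tumble segmentation, tumbling bias, chemotactic drift, directional
    run statistics, spreading bias); FRET ratio processing with kinase
    activity calibration and Hill dose-response fitting; and synthetic-data
    generators so every pipeline stage is testable without experimental
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
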