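Package: chemotaxr
Title: Quantifying Neutrophil Chemotaxis in Microfluidic Gradient Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cell chemotaxis in microfluidic gradient
    channels: a one-dimensional co-flow gradient model, a ground-truthed
    synthetic assay simulator (gradient-biased von Mises random walks,
    rendered cell fields, synthetic COPD/control cohorts), automated cell
    detection and track linking, trajectory statistics (chemotactic index
    and migration speed), image-moment ellipse morphometry, and the cohort
    statistics (group tests, spirometry regression, leave-one-out scans)
    used to relate chemotaxis to lung function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    grid,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
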