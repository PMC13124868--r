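Package: ramanscreen
Title: Exhaustive Screening of Raman Spectral Preprocessing for Bioprocess Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the best combination of Raman spectral preprocessing
    filters for soft-sensing biochemical parameters in cell-culture
    bioprocesses. Provides a library of 19 filter operators in four
    categories (smoothing, baseline correction, normalization, other), an
    exhaustive screen of all 480 category combinations through partial
    least squares (PLS) and multilayer-perceptron (ANN) calibration
    models, full-factorial modelling of the resulting prediction-error
    metrics, and Derringer desirability optimization that recommends the
    best filter combination per parameter and overall. Includes a
    synthetic insect-cell bioprocess generator (five batch runs, growth
    and infection kinetics, linear concentration-to-peak spectral mixing,
    fluorescence background, detector noise) so the whole workflow is
    runnable and testable without instrument data.
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
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
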