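Package: vertefail
Title: Vertebra-Specific Incidental Fracture Prediction from Quantitative CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting incidental osteoporotic
    vertebral fractures from routine CT. Provides phantom-calibrated trabecular
    bone mineral density (BMD) measurement, Hounsfield-unit driven nonlinear
    finite-element estimation of vertebral failure load and failure
    displacement, global (L1-3) and local (regional) normalization ratios, and
    ROC-based discrimination of to-be-fractured vertebrae, together with a
    synthetic CT cohort generator used to exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
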