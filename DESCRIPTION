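Package: llca
Title: Longitudinal and Parallel-Process Latent Class Models for Childhood Constipation and Soiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits longitudinal latent class models (LLCA) to repeated binary
    symptom indicators with missing data via EM with multiple random starts,
    joins two symptom processes (constipation and soiling) in a parallel-process
    model with a 4x4 joint class distribution, collapses the sixteen joint
    classes into four clinically interpretable composite groups, and regresses
    composite class membership on early-childhood risk factors using the
    bias-adjusted three-step multinomial logistic approach. Includes a
    synthetic cohort generator calibrated to a large UK birth cohort so the
    whole pipeline can be exercised against known ground truth, plus broom-style
    tidiers and ggplot2 visualisations.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
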