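Package: pdus
Title: Non-Contrast Power-Doppler Ultrasound Perfusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pipeline for quantifying skeletal-muscle perfusion from
    non-contrast power-Doppler ultrasound (PD-US). Assembles slow-time
    ensembles of radiofrequency echo frames, removes rigid in-plane tissue
    motion with sub-sample precision, separates tissue clutter from blood
    echoes by singular-value decomposition of the space-time (Casorati)
    matrix, and converts filtered echo power into baseline-normalized
    perfusion profiles. Includes estimators for the ischemic-response
    parameters of a hindlimb-ligation model (20-min perfusion spike, minimum
    perfusion, recovery time), endothelial-function indices (flow-mediated
    dilation and reactive hyperemia), the accompanying statistical
    procedures (Box-Cox transformation, rank tests with exact small-sample
    enumeration, rank-based permutation ANCOVA, glucose-tolerance
    classification), and a synthetic RF-speckle and cohort simulator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    MASS,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
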