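Package: sigbridge
Title: Cross-Platform Rank-Based Immune Signature Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample, rank-based scoring of immune gene signatures on
    targeted-panel (NanoString-style) and whole-transcriptome expression data,
    with three ranking calibrations (uncalibrated, stable-gene stratified, and
    linearly skewed ranks), an emulation of the documented NanoString
    normalisation chain, cross-platform gene-rank consistency diagnostics,
    responder differential testing, cross-platform score-agreement analysis,
    and a stability-selected penalized-logistic response predictor. Includes a
    synthetic paired-platform cohort generator with known ground truth so the
    full pipeline is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
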