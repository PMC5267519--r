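Package: riscal
Title: Relative Induction Score Calibration for CYP3A4 Induction DDI Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts clinical CYP3A4 induction-mediated drug-drug interactions
    from in vitro concentration-response data using the relative induction
    score (RIS) approach. Converts replicate enzyme-activity or qPCR (2^-ddCt)
    measurements into QC-filtered fold-increase points, fits sigmoidal Hill
    4-parameter induction curves with plateau-aware Emax/EC50 extraction,
    computes RIS from unbound plasma Cmax, calibrates RIS against observed
    midazolam AUC changes with a Hill 3-parameter model, derives the RIS
    cutoff at a 20% AUC change, and evaluates prediction accuracy with RMSE
    and geometric mean fold error. Includes a synthetic panel generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr,
    rmarkdown
Config/testthat/edition: 3
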