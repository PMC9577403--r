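Package: pvsignals
Title: Disproportionality Signal Detection for Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests spontaneous adverse drug reaction (ADR) line listings,
    expands reports into drug-event pairs, builds 2x2 disproportionality
    contingency tables, and computes four signal-detection statistics --
    proportional reporting ratio (PRR), reporting odds ratio (ROR), the
    MHRA joint criterion (PRR, case count, Pearson chi-square), and the
    Bayesian confidence propagation neural network (BCPNN) information
    component -- with signal-strength classification. Includes a
    method-comparison framework (confusion tables, sensitivity,
    specificity, predictive values, Youden index, case-count threshold
    sweeps, ROC/AUC) against a configurable reference method, a synthetic
    spontaneous-report generator with planted associations for validation,
    descriptive summaries, and a file-based analysis pipeline with a
    command-line wrapper.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
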