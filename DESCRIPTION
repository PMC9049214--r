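Package: abxeval
Title: Appropriateness Evaluation of Outpatient Antibiotic Prescribing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the appropriateness of outpatient antibiotic
    prescriptions from visit-level electronic prescribing records. Diagnoses
    are mapped to a three-tier indication scheme over 30 diagnostic
    categories (with separate handling of traditional Chinese medicine
    codes), antibiotics are identified from the ATC catalogue and labelled
    with spectrum and WHO AWaRe class, and each antibiotic-prescribing visit
    receives one of four appropriateness categories. Estimation utilities
    cover Clopper-Pearson exact binomial intervals, Goodman simultaneous
    multinomial intervals, diagnosis-spectrum direct standardization, and
    random-intercept logistic models for inappropriate prescribing.
    Interrupted time-series tools build monthly outcome series, seasonally
    adjust them by classical decomposition, fit segmented regressions with
    Newey-West errors, and run Durbin-Watson and Breusch-Godfrey style
    autocorrelation diagnostics. A synthetic-records generator with full
    ground-truth bookkeeping lets the whole pipeline run without access to
    any real prescribing database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
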