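Package: diabscreen
Title: Microsimulation of Large-Scale Diabetes Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a stratified synthetic adult population from cohort-study
    summaries via inverse-variance mixed-effects meta-regression, applies
    questionnaire risk scores (Chaturvedi, Mohan/IDRS, Ramachandran) and random
    capillary glucometer screening with measurement error, and reports national
    screening performance (sensitivity, specificity, predictive values, number
    needed to screen), health-system burden, discounted program costs, ROC
    cut-point recalibration, complication-prevention yield under best-case
    treatment, and Monte Carlo credible intervals for all outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    metafor,
    MASS,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
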