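Package: luscab
Title: Clinical-Ultrasound Prognostic Score Validation for Infant Bronchiolitis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for the modified Wood-Downes-Ferres clinical severity
    score and the LUSCAB score (lung ultrasound findings, clinical data and age
    in bronchiolitis), together with the full validation pipeline for a
    prognostic cutoff in infants assessed for acute bronchiolitis in the
    emergency department: confusion matrices and sensitivity, specificity and
    predictive values at a cutoff, empirical ROC curves with DeLong confidence
    intervals for the area under the curve, Kaplan-Meier time-to-respiratory-
    support curves compared by the log-rank test, descriptive cohort tables,
    and a calibrated latent-severity simulator that generates synthetic
    cohorts with the marginal structure of the study population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
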