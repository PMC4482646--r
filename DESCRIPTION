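Package: gestagree
Title: Agreement of Gestational Age Estimation Methods with Crown-Rump
    Length Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies bias and 95% limits of agreement of alternative
    gestational age estimation methods (Dubowitz newborn assessment,
    serial symphysis-fundal height formula, head-circumference and
    biparietal-diameter ultrasound biometry) against crown-rump-length
    dating. Provides dating formulas from fetal biometry, a moment-based
    replicated-measurement limits-of-agreement estimator whose intervals
    predict a single future measurement, bias-prediction equations for
    use without crown-rump length, preterm misclassification analysis
    (Cohen's kappa, sensitivity, specificity with exact intervals), and
    a synthetic obstetric cohort generator with the variance structure
    the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
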