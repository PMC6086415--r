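Package: nccreri
Title: Additive Interaction in Nested Case-Control Analyses of Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying additive interaction between time-varying
    drug exposures and comorbidity profiles in nested case-control analyses
    of longitudinal healthcare claims. Provides a synthetic claims-data
    generator with known ground-truth effect and interaction structure,
    new-user cohort assembly with washout and age rules, acute myocardial
    infarction outcome ascertainment from hospital discharge codes,
    dispensing-to-episode exposure construction with current/recent/past/none
    classification under alternative parametrizations, risk-set matched
    control sampling, conditional logistic regression fitted from the
    conditional likelihood by Newton-Raphson, and the relative excess risk
    due to interaction (RERI) with delta-method confidence intervals,
    joint-effects classification, and a staged product-term model-building
    procedure with AIC selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
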