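Package: ansig
Title: Automatic Number Series Item Generation and Explanatory Item
    Response Modelling
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based generation of number-series inductive reasoning
    items from thirteen item models built on five cognitive operators
    (apprehension of succession, parallel sequences, cluster formation,
    non-progressive and progressive coefficient patterns), together with
    the explanatory item response theory machinery used to calibrate and
    predict item difficulty: Rasch calibration by conditional maximum
    likelihood with elementary symmetric functions, Andersen likelihood
    ratio and Wald item fit tests, test information and person separation
    reliability, linear logistic test models (LLTM) with and without an
    item error term fitted as generalised linear mixed models, parametric
    bootstrap standard errors, Q-matrix design tools, respondent
    simulation under missing-by-design multi-form layouts, and
    disattenuation utilities for validity reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    glmmTMB,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
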