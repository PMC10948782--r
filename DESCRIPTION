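Package: glucocog
Title: Dynamic Within-Person Coupling of Glucose and Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how naturally occurring glucose fluctuations
    relate to moment-to-moment cognitive performance in type 1 diabetes.
    Includes a synthetic-study generator (AR(1) continuous glucose monitoring
    streams, ecological momentary assessment sessions with trial-level task
    records, and a person-level feature table with known ground truth), CGM
    cleaning and glycemic summary metrics, scoring and quality control for
    digit-symbol matching and go/no-go task sessions, multilevel reliability
    estimation, a hierarchical Bayesian random quadratic-slope model of
    cognition on within-person scaled glucose with equivalence (ROPE) tests
    and optimal-performance localization, and repeated cross-validated lasso
    stability selection of person-level predictors of cognitive vulnerability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    glmnet,
    lme4,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
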