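Package: cesofa
Title: Derivation and Validation of Cardiac-Extended SOFA Scores in Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive, weight and validate cardiac extensions of the
    Sequential Organ Failure Assessment (SOFA) score for 30-day mortality
    prediction in sepsis. Implements spline-based screening of cardiovascular
    variables, AIC-driven flexibility selection, ordinal point transformation
    with balanced effect sizes, component-substitution logistic models,
    enumeration and selection of weighted score extensions, and the
    accompanying inferential machinery (logistic maximum likelihood, AUC with
    DeLong confidence intervals, paired DeLong tests, category-free net
    reclassification improvement, Hosmer-Lemeshow calibration, and
    AUC-based sample-size calculation). A seeded synthetic sepsis cohort
    generator makes the full pipeline testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
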