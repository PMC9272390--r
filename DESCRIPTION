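Package: adipomr
Title: Multivariable Mendelian Randomization for General and Central Adiposity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate the direct metabolic effects of general
    adiposity (body mass index) from central adiposity (waist-to-hip ratio)
    using genetic instruments. Implements genetic risk score construction
    from allele dosages, univariable and multivariable two-stage least
    squares with heteroskedasticity-robust standard errors, logistic second
    stages for medication outcomes, product-term interaction tests,
    Sanderson-Windmeijer conditional instrument-strength statistics,
    summary-level two-sample estimators (inverse-variance weighted,
    MR-Egger, weighted median, weighted mode) with allele harmonisation,
    and an analysis pipeline covering sex, medication and age-tertile
    stratification. A seeded synthetic cohort generator reproduces the
    assumed causal structure, including statin use as a collider between
    adiposity and measured LDL cholesterol, so every stage is testable
    without access to individual-level biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
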