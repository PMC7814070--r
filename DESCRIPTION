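Package: gonref
Title: Objective Structural-Functional Reference Standard and Diagnostic
    Evaluation for Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rule-based objective reference standard for
    glaucomatous optic neuropathy (GON) that requires corresponding
    structural (SDOCT peripapillary RNFL) and functional (SAP 24-2)
    damage, together with the evaluation machinery for continuous
    diagnostic scores graded against it: quality-control and temporal
    pairing of exams, hemifield mean-deviation normative cutoffs,
    three-way classification (glaucoma / normal / suspect) with
    Hodapp-Parrish-Anderson severity staging, pooled and age-adjusted
    ROC analysis via placement values, eye-level clustered bootstrap
    confidence intervals, interval likelihood ratios with Bayesian
    post-test probability updating, weighted-kappa agreement with
    subjective gradings, and a seeded synthetic cohort generator that
    emulates the statistical structure of a clinical registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
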