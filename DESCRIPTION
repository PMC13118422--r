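Package: carbodose
Title: Carboplatin Dosing by Meta-Analytic Population Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pools published population-pharmacokinetic parameter estimates of
    carboplatin by inverse-variance random-effects meta-analysis, predicts
    exposure (AUC over 24 h) under Calvert-type dose formulas with a
    closed-form two-compartment infusion model, and evaluates modified Calvert
    formulas (an additive constant added to the non-renal clearance term) by
    probability-of-target-attainment criteria.  Includes renal-function
    estimators (Cockcroft-Gault, CKD-EPI), body-surface-area formulas, a
    seeded virtual-cohort generator for breast-cancer patients with preserved
    renal function, and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    metafor,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
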