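Package: hsindex
Title: Hemodynamic Stability Index for ICU Early Warning
Version: 0.1.0
Authors@R: person("HSI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Builds an interpretable early-warning score for hemodynamic
    instability in intensive-care patients. Treatment records (vasopressor and
    inotrope starts, fluid boluses, packed red blood cell transfusions) are
    converted into labeled intervention segments by a rule-based cumulative-dose
    labeler; a 33-variable physiological snapshot is constructed at arbitrary
    query times with forward-fill staleness limits and a clinical imputation
    policy; a gradient-boosted ensemble of depth-one decision stumps produces an
    additive per-variable risk score with Platt-scaled probabilities, the
    Hemodynamic Stability Index (HSI), bootstrap confidence intervals and an
    abstention rule; and the evaluation layer reports ROC/PR summaries,
    breakeven and fixed-specificity operating points, operating-mode, lead-time
    and subgroup breakdowns. A seeded synthetic ICU cohort generator makes the
    whole pipeline testable without access to credentialed clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
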