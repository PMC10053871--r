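Package: ccwrisk
Title: Target Trial Emulation with Clone-Censor-Weight and Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates a target trial from hospital-based observational
    cohorts using the clone-censor-weight design with a treatment grace
    period. Each admission is cloned into both treatment strategies,
    clones are artificially censored on protocol deviation within the
    grace period, and inverse-probability-of-censoring weights from
    per-arm Cox models undo the induced selection. Outcomes (in-hospital
    death and its competing event, discharge alive) are analysed with
    constant cause-specific hazards estimated by weighted pooled logistic
    regression, closed-form cumulative incidence functions, risk
    differences and ratios, and expected lengths of stay. Weighted
    Nelson-Aalen and Aalen-Johansen estimators and a naive Kaplan-Meier
    comparator quantify competing-risks bias; confidence intervals come
    from a patient-level bootstrap. A discrete-time cohort simulator with
    confounded treatment initiation provides ground-truth oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
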