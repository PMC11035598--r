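Package: sensebias
Title: Ranking-Bias Audits for Smartphone-Sensing Depression Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to audit algorithmic ranking bias in machine-learning
    models that predict clinically-significant depression (PHQ-8 >= 10)
    from passively sensed smartphone behavior. Provides a seeded synthetic
    cohort generator with known, subgroup-specific behavior-outcome
    couplings (GPS fixes, screen events, PHQ-8 self-reports); extraction of
    standard mobility, phone-usage and sleep features over 14-day windows;
    subject-partitioned repeated cross-validation over a grid of calibrated
    classifiers; Subgroup/BNSP/BPSN AUC ranking-bias metrics with
    trial-percentile confidence intervals; generalized estimating equations
    to isolate subgroup effects on predicted risk; and permutation-sampling
    Shapley attributions compared against per-subgroup explanatory logistic
    slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    ranger,
    sandwich,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
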