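Package: linacsched
Title: Radiotherapy Treatment-Time Prediction and Minute-Granular Linac Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-fraction radiotherapy positioning time (PT) and
    treatment time (TT) from positioning and plan-complexity features, and
    packs the predicted durations into a minute-granular linac schedule.
    Provides a reproducible synthetic-cohort generator, deep feature
    synthesis over relational entity sets (direct, entity and relational
    feature primitives), cross-validated model selection and hyperparameter
    tuning over a small candidate family, a tolerance-band accuracy
    statistic, a multiple-linear-regression baseline with published
    reference coefficients, a two-level slot scheduler (hour-sized blocks of
    one-minute unit slots) with traffic-light capacity indicators and
    non-treatment task placement, a fixed-block scheduling baseline for
    comparison, and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    ranger,
    glmnet,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xgboost
Config/testthat/edition: 3
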