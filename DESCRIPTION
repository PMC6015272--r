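Package: trialcea
Title: Within-Trial Cost-Effectiveness Analysis for Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for trial-based economic
    evaluation of a web-based diabetes self-management programme versus usual
    care: micro-costing of a digital intervention into fixed annual and
    per-user components, health-service costing from resource-use counts and
    national unit costs, EQ-5D-3L utility scoring with the UK TTO tariff,
    PAID diabetes-distress scoring, QALYs by area under the utility curve,
    multiple imputation by chained equations with predictive mean matching,
    baseline-adjusted incremental cost and effect estimation with random
    centre effects pooled by Rubin's rules, nonparametric bootstrap
    uncertainty (cost-effectiveness plane and acceptability curve), and
    one-way user-scaling sensitivity analysis with break-even user counts.
    Includes a calibrated synthetic trial generator so the whole pipeline is
    testable without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
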