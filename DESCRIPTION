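Package: paimatch
Title: Personalized Advantage Index Treatment Matching for Two-Arm
    Guided Self-Help Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the personalized advantage index (PAI) analysis
    pipeline for two-arm patient-preference trials of guided self-help:
    per-arm variable selection by Boruta shadow-feature random forests and
    elastic-net penalized regression, leave-one-out cross-validated linear
    outcome models, counterfactual PAI computation with optimal/non-optimal
    classification and a large-benefit subgroup rule, and the endpoint
    statistics (reliable and clinically significant improvement, 2x2
    chi-square tests and odds ratios, pooled t tests from summaries, and
    mixed repeated-measures ANOVA with Mauchly/Greenhouse-Geisser
    sphericity handling). Includes a synthetic preference-trial generator
    with known per-patient treatment effects for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
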