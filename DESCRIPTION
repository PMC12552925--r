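Package: petcea
Title: Cost-Effectiveness and Value-of-Information Analysis of PSMA-PET
    Imaging Strategies for Biochemically Recurrent Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing diagnostic imaging strategies
    (up-front PSMA-PET, PSMA-PET as a reflex test after negative conventional
    imaging, and conventional CT plus bone scintigraphy) for biochemically
    recurrent prostate cancer. Couples a diagnostic-accuracy decision tree to a
    ten-state Markov cohort model, computes discounted lifetime quality-adjusted
    life-years and costs, ranks strategies on the incremental
    cost-effectiveness frontier with strong and extended dominance, propagates
    parameter uncertainty by seeded Monte Carlo simulation
    (cost-effectiveness acceptability curves), and quantifies the expected
    value of perfect and partial perfect information with population-level
    scaling. Ships a transcription of the published model inputs, PSA-level
    stratified analyses, and an individual-level micro-simulation oracle for
    validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv,
    rlang
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
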