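Package: icbtcea
Title: Cost-Effectiveness Analysis of Guided Internet-Based CBT for Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-utility analysis of a guided internet-based cognitive
    behavioural therapy (iCBT) programme for major depressive disorder using
    a three-state (remission, depression, death) discrete-time Markov cohort
    model. Background mortality comes from sex-stratified annual life tables
    with a hazard-scale relative-risk adjustment for the depression state;
    transition probabilities and state utilities can be estimated from paired
    baseline/post PHQ-9 scores. The package computes discounted and
    nondiscounted lifetime costs and QALYs from healthcare and societal
    perspectives, incremental cost-effectiveness ratios and dominance classes,
    deterministic sensitivity analyses (session-cost reduction and
    effect-discount-rate sweeps with willingness-to-pay intersection), a
    synthetic-data generator for life tables and PHQ-9 cohorts, and an
    individual-level microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
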