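Package: bktrial
Title: Simulation and Analysis of Adaptive-Feedback Learning Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adaptive feedback in self-directed,
    game-based training of health care providers. Implements the
    Bayesian Knowledge Tracing (BKT) learner model with grid-search and
    EM fitting, a threshold feedback policy driven by the predicted
    probability of next-attempt success, a generative simulator of a
    two-arm randomized trial (learner covariates, coin-flip allocation,
    spacing-dependent forgetting, per-round dropout), scoring and
    normalized learning gains, single-group and pretest-posttest-control
    (Morris G) effect sizes, OLS regression of gains with diagnostics,
    attrition and variance-homogeneity tests, and power/sample-size
    calculators, together with JSONL/CSV event-log input/output and a
    small command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    lmtest,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
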