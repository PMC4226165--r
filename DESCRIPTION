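Package: explorentropy
Title: Entropy-Based Exploration Metrics and Brain-Autonomic Coupling for
    Stochastic Decision-Making Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying exploration in two-option stochastic
    decision-making tasks with a smoothed conditional-entropy statistic of
    Stay/Shift behavior, and for linking it to peripheral sympathetic activity
    and regional brain activity. Includes a task simulator with generative
    choice policies (Win-Stay/Lose-Shift, outcome-conditioned, Q-learning
    softmax), frequency-domain heart-rate-variability features from interbeat
    intervals (4 Hz resampling, periodogram, LF/HF band powers),
    task-minus-baseline change scores, correlation, stepwise-regression and
    repeated-measures-ANOVA linkage statistics with Greenhouse-Geisser
    correction, ROI-level covariate correlation and seed connectivity, and a
    synthetic cohort generator with configurable brain-autonomic correlation
    structure for ground-truth validation of every pipeline stage.
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
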