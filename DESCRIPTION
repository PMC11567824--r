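Package: cogrisk
Title: Simulation and Risk-Factor Association Analysis for Smartphone Cognitive Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how modifiable dementia risk factors relate to
    objective and subjective cognition measured with brief gamified smartphone
    tasks. Provides a seeded synthetic-cohort generator with configurable
    marginal distributions and injected standardized effects, trial-level
    simulators for a visual working-memory binding game, a trail-making style
    flexibility game, and a two-step reinforcement-learning planning game,
    exact chance-level accuracy enumeration and task scoring with outlier
    censoring, per-subject model-based planning indices from stay/switch
    logistic regressions (with optional empirical-Bayes shrinkage), and a
    standardized-coefficient regression suite (primary, binarized,
    depression-adjusted, and age-interaction analyses) with per-outcome
    Bonferroni correction. Results are tidy tibbles with tidy()/glance()
    methods and ggplot2 autoplot() displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
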