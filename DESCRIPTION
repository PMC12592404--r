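Package: ctbayes
Title: Bayesian Ideal-Observer Analysis of Central Tendency in Magnitude
    Reproduction
Version: 0.1.0
Authors@R:
    person("ctbayes", "maintainers", email = "ctbayes@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for central-tendency (regression to the mean)
    effects in auditory and visual duration and length reproduction tasks.
    Provides a synthetic-observer generator with configurable Bayesian
    generative regimes, response normalization and outlier screening,
    psychometric estimation (regression index, intercept bias, per-stimulus
    sensory precision corrected for central tendency, modality reliability
    weights), truncated-normal prior moment matching by constrained
    optimization, four ideal-observer models with modality-specific or
    supra-modal priors, and linear mixed-model comparison of model
    predictions by AIC/BIC with cross-validated predicted R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
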