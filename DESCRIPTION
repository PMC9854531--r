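Package: fiplearn
Title: Simulation and Inference for Surprise-Gated Learning in Changepoint Estimation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the frog-in-the-pan effect in predictive
    inference: greater sensitivity to abrupt than to gradual changes of a
    tracked quantity. Provides generators for two-block changepoint
    estimation task schedules (gradually versus abruptly drifting Gaussian
    targets), a generative cohort of delta-rule agents whose effective
    learning rate is either condition-dependent or a piecewise-linear
    function of the absolute prediction error with an unknown breakpoint,
    trial-level metrics (prediction error, update, empirical learning rate,
    reaction-time exclusion), and the matching inference battery:
    condition-by-prediction-error mixed linear models, a quadratic
    nonlinearity check, a segmented (broken-line) mixed model with profile
    likelihood breakpoint estimation, a threshold-exceedance logistic
    regression, and a reaction-time mixed model, plus a parameter-recovery
    harness and a reproducible simulate-analyze-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
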