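Package: interactsim
Title: Monte-Carlo Study of Interaction Effects and Misspecification Bias
    in Linear Regression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study what happens when a linear regression model
    omits a true interaction (moderation) term. Generates finite synthetic
    populations with a known interaction structure between two correlated
    normal predictors, fits correctly specified (interaction) and
    misspecified (simple-effects) ordinary least-squares models to repeated
    samples, and quantifies estimation bias, statistical power, overfit,
    and out-of-sample generalizability via population R-squared. Includes
    the closed-form expected coefficients of the misspecified model, the
    Cohen f-squared effect size of the interaction, leave-one-out
    cross-validated R-squared as a practical proxy for population
    R-squared, and a seeded, resumable experiment runner over the full
    simulation grid with tidy CSV/JSON reporting and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
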