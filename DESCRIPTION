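Package: twostagesim
Title: Simulation and Analysis of Two-Stage Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates model-free (SARSA(lambda)) and model-based
    reinforcement-learning agents performing two-stage ("two-step")
    decision tasks under configurable transition structures and reward
    schedules (drifting Gaussian random walks with reflecting bounds,
    fixed probabilities, and probability-swap schedules), and analyzes
    the resulting choices with the standard stay-probability logistic
    regressions. Includes closed-form results on when a main effect of
    transition appears in model-based behavior, preset experiment
    configurations, and a command-line interface for reproducing the
    full set of simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
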