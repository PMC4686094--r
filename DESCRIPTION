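Package: twostepr
Title: Simulation and Analysis of the Two-Step Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Generative models of the original and reduced two-step
    decision tasks, a family of reinforcement-learning agents (Q-lambda
    model-free, model-based with known or learned transitions,
    reward-as-cue, and Bayesian latent-state agents), and the analysis
    stack used to characterise their behaviour: stay-probability tables,
    one-trial-back and lagged logistic regressions of choice with
    'correct'-choice corrections, maximum-likelihood model fitting with
    cross-fit likelihood matrices and BIC, and reward-rate parameter
    optimisation with common random numbers. Trial-level simulation and
    likelihood evaluation share a single compiled code path so that
    fitted models are evaluated exactly as simulated ones.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
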