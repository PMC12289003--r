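Package: promediate
Title: Bayesian Mediation Analysis of Chatbot-Collected Patient-Reported Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for evaluating Bayesian causal mediation
    analysis on patient-reported outcomes (PROs) gathered through a branching
    chatbot conversation. Generates synthetic cohorts from a linear-Gaussian
    mediation data-generating process (treatment -> adverse-event severity ->
    fatigue, with stress as an outcome covariate), renders each subject as a
    multi-turn patient-chatbot transcript, parses transcripts back into an
    analysis table, fits the two-equation mediation model with a conjugate
    blocked Gibbs sampler, decomposes the treatment effect into direct,
    indirect and total components with equal-tailed credible intervals, and
    scores estimator quality (bias, RMSE, coverage, interval width) over
    replicated simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
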