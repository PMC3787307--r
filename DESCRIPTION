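Package: igtEV
Title: Expectancy-Valence Modelling of Iowa Gambling Task Behavior in
    Longitudinal Smoking Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cognitive modelling of the Iowa Gambling Task (IGT)
    with the revised Expectancy-Valence (rEV) learning model: a deterministic
    payoff engine for the four standard decks, per-subject maximum-likelihood
    fitting of the three rEV parameters (attention weight to gains, recency,
    choice consistency), comparison against a static baseline choice model via
    a BIC statistic, generative simulation and parameter-recovery experiments,
    behavioral net-score metrics, a calibrated two-wave synthetic cohort
    generator, and the downstream epidemiological analysis stage (contingency
    tests, t-tests, split-plot block-by-group contrasts, and adjusted
    logistic/linear prediction models of follow-up smoking outcomes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
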