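Package: mctrialsim
Title: Simulation-Based Design of Multicenter Binary-Outcome Trials with
    Treatment-by-Center Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing multicenter two-arm randomized trials with a
    binary outcome when the control-arm event probability varies between
    centers (treatment-by-center interaction). Provides a moment-matched Beta
    model for the between-center distribution of an event probability, a
    seeded trial simulator with stratified-blocked randomization, a
    DerSimonian-Laird random-effects analysis on the risk-difference scale,
    empirical power estimation with grid search for the required sample size,
    a closed-form variance of the estimated treatment effect with sensitivity
    analyses, and a Bayesian decision model that converts a trial's
    surrogate-outcome effect into a posterior probability that treatment
    reduces a rare clinical outcome, using external surrogate-link counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
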