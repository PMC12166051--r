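Package: ynat
Title: Simulation and Repetition-Bias Modelling for the Y-Navigation Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying choice perseveration (Thorndike's law of
    exercise) in a sequential decision task. Provides a simulator of the
    Y-navigation grid-world task (a 5-by-5 grid navigated with four
    diagonal/down moves to collect points matching a trial-specific goal),
    a family of categorical choice models combining precision-weighted
    expected reward with a count-based repetition prior over action
    sequences, Bayesian parameter estimation (MAP, Laplace and MCMC) under
    weakly informative priors, PSIS-LOO model comparison, behavioral
    summary statistics, posterior predictive checks, and parameter- and
    model-recovery pipelines exercised on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
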