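Package: costedbayes
Title: Costed-Bayesian Modelling of Sequential Information Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the beads/fish information-sampling task with explicit
    sampling costs. Implements the belief-state (partially observable Markov
    decision process) model of the task: Bayesian posteriors over the two
    sources, action values for declaring or sampling, backward-induction value
    tables, softmax choice, and ideal-agent policy statistics. Provides a
    synthetic cohort generator with gamma-distributed subject-level cost and
    temperature parameters, hierarchical expectation-maximization estimation
    of group-level gamma distributions, integrated BIC comparison of combined
    versus separate group models, and behavioural summaries (draws to
    decision, Bayesian accuracy, jumping-to-conclusions classification,
    intraclass correlations, nonparametric group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
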