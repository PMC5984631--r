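Package: waitbayes
Title: Bayesian Decision Modelling of Waiting for Delayed Rewards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how an agent decides to keep waiting for a
    delayed, probabilistic reward. Implements a Bayesian sequential wait-or-quit
    decision model (Gaussian or mixture beliefs about reward timing, softmax
    action selection, a discrete-time quit-time recursion), a simulator of the
    sequential tone-food waiting task used in optogenetic studies of dorsal
    raphe serotonin neurons, the associated behavioural analysis pipeline
    (omission-trial waiting-time ratios, Scheirer-Ray-Hare rank test,
    Bonferroni-corrected pairwise tests, parametric-bootstrap likelihood-ratio
    test for a mouse-level variance component), and maximum-likelihood fitting
    of model parameters to censored quit-time data with parameter-recovery
    diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
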