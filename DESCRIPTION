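Package: herdpool
Title: Dyadic Herder Risk-Pooling Simulations with Need-Based and
    Account-Keeping Livestock Transfers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of risk pooling between two East African
    pastoralist households facing stochastic herd growth and catastrophic
    losses from drought and disease. Implements three livestock-transfer
    institutions as decision rules -- no exchange, need-based transfers
    (ask only in need, give if able; the Maasai osotua idiom), and
    account-keeping transfers (loans with debt, credit limits and expected
    repayment; the esile idiom) -- together with experiment drivers for
    within-pair survival correlations, environmental volatility and
    generosity sweeps, a survival payoff matrix with a dominance check, and
    wealth-inequality summaries (Gini coefficient, Lorenz curves). All
    experiments are reproducible Monte-Carlo runs driven by a single base
    seed; a fast C++ engine and a pure-R reference engine produce
    bit-identical trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
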