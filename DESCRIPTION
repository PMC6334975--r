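Package: coeruleus
Title: Active Inference Simulation of Locus Coeruleus Firing and Adaptive Model Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active inference (POMDP) agents whose belief
    updating yields a state-action prediction error: the Kullback-Leibler
    divergence between Bayesian model averages over hidden states at
    successive time steps. The error drives a simulated locus coeruleus
    spiking unit (logistic rate, Bernoulli bins) and adaptively sets the
    decay rate of the agent's Dirichlet-parameterised world model, so that
    phasic and tonic noradrenergic firing modes and flexible relearning
    after contingency reversals emerge from a single mechanism. Includes
    generative models and simulation protocols for a Go/No-go reward
    learning task (with cue reversal) and a three-arm explore/exploit
    bandit, plus tidy summaries, permutation tests and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
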