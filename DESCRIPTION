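Package: hafvf
Title: Actor-Critic Reinforcement Learning with Hierarchical Adaptive Forgetting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian reinforcement learning for volatile environments. The
    critic is a hierarchical adaptive forgetting variational filter: a
    Normal-Inverse-Gamma belief over each state-action reward whose learning
    rate is governed by Beta-distributed forgetting factors, themselves
    learned from the data by non-conjugate variational message passing. The
    actor is a Normal-Inverse-Gamma diffusion model that samples drift and
    accumulation noise from the critic's posterior and converts them into
    choices and reaction times through a drift-diffusion race. The package
    simulates reward streams, bandit and Markov-decision-process tasks, fits
    agent priors and diffusion parameters to choice/reaction-time data by
    amortized variational inference with MAP optimisation, and computes
    Laplace approximations of the log model evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
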