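Package: psnav
Title: Interpretable Projective-Simulation Swarm Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of collective navigation in which a swarm of
    identical agents learns, through a transparent tabular projective-simulation
    memory with glow-based eligibility, to self-organize into longitudinal
    queues while travelling to a distant target. Provides the shared
    state-action memory and its learning rules, a two-dimensional unbounded
    swarm environment with topological neighbor perception and discretized
    steering actions, macroscopic order parameters (polarization and
    motion-aligned elongation), a weighted Vicsek baseline, policy
    interpretability tools (entropy, certainty, deterministic rule extraction),
    and reproducible training, evaluation, sensitivity and robustness
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
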