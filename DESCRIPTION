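Package: hexnav
Title: Deep Reinforcement Learning of Allocentric and Egocentric Navigation
    in Hexagonal-Grid Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how navigation
    strategies and spatial representations emerge in deep reinforcement
    learning agents. Provides hexagonal-lattice arenas with procedurally
    rendered panoramic visual observations, guidance (fixed hidden goal) and
    aiming (visibly cued goal) tasks, allocentric/egocentric/combined action
    spaces, a convolutional dueling double deep Q-network trained with
    experience replay, rate-map computation and classification of hidden
    units into place, egocentric-vector, head-direction-modulated and
    view-selective types, coverage-entropy analysis, noise-injection
    lesions, and generalization experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
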