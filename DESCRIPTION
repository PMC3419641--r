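Package: sdds
Title: Stochastic Discrete Dynamical Systems for Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, analysing and simulating stochastic discrete
    dynamical systems (SDDS): multi-valued logical networks in which every
    node carries an update rule together with an activation and a degradation
    propensity, so that a called-for increase (decrease) of a node's level
    occurs only with the corresponding probability.  The package represents
    models as truth tables over a finite multi-valued state space, computes
    the exact one-step transition kernel and the full weighted state-transition
    graph, enumerates fixed points and attractors (terminal strongly connected
    components), propagates exact state distributions, and samples single-cell
    trajectories and cell-population summaries to study cell-to-cell
    variability.  Ships logical models of the p53-Mdm2 damage-response network
    and of the phage lambda lysis/lysogeny switch, a two-variable textbook
    example, a random model generator for property-based testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
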