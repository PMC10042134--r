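Package: gcsim
Title: Stochastic Agent-Based Simulation of the Germinal Center Reaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatial, stochastic agent-based model of the germinal center
    (GC) reaction for studying how antigen availability on follicular
    dendritic cells, founder-cell affinity, antibody feedback, and the
    quantity and quality of T follicular helper (Tfh) cells shape the
    temporal evolution of B-cell clonal diversity. B cells carry receptors
    encoded in an abstract shape space; affinity maturation emerges from
    somatic hypermutation in the dark zone and competitive, Tfh-limited
    selection in the light zone. The package computes founder-cell Shannon
    entropy, clonal dominance and the cumulative GC response from simulated
    clone censuses, provides preset perturbation experiments with replicate
    and seed management, and includes a fixture generator for testing the
    metrics layer independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
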