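Package: vsdkinetics
Title: Conformational Kinetics of Voltage-Sensing Domains from Trajectory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the activation of voltage-sensing domains
    (VSDs) from molecular trajectory data: trajectory reading and
    featurisation, average-linkage RMSD clustering, time-lagged independent
    component analysis (tICA), reversible Markov state model estimation with
    Chapman-Kolmogorov validation, PCCA+ metastable coarse-graining,
    mean-first-passage-time kinetics and transition-state-theory free-energy
    barriers, per-state ion-pair and hydrogen-bond occupancy tables, S4
    axial-displacement metrics, and Boltzmann activation-curve fitting of
    voltage-clamp recordings. A synthetic-data module generates metastable
    Langevin trajectories, sliding-helix structural fixtures with planted
    contacts, and current-voltage sweeps with known ground truth, so every
    stage of the pipeline is verifiable without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
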