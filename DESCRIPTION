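Package: forcepaths
Title: Unfolding Kinetics from Single-Molecule Force Spectroscopy and
    Force-Propagation Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two computational arms of a single-molecule
    protein-mechanics study. The force-spectroscopy arm simulates
    constant-velocity AFM pulling of multidomain constructs with Bell-model
    unfolding kinetics, detects unfolding peaks in force-extension curves,
    fits each rising stretch with the worm-like-chain model, converts fitted
    contour lengths into contour-length increments and class assignments,
    estimates most-probable unfolding forces by kernel density estimation
    with a Silverman-type bandwidth rule, and fits the Bell-Evans dynamic
    force spectroscopy model to recover intrinsic unfolding rates,
    transition-state distances, Arrhenius barrier heights and critical
    forces. The network arm builds occupancy-filtered, correlation-weighted
    residue-interaction networks from coordinate trajectories, computes
    closeness and betweenness centrality, and enumerates optimal and
    suboptimal force-propagation paths with a Floyd-Warshall-based bounded
    search, including merging of path sets from multiple pulling points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
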