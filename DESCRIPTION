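Package: tunnelr
Title: Protein Tunnel Detection and Discretized Ligand Transport Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric detection and characterization of tunnels in protein
    structures via a clearance-annotated Voronoi network and lowest-cost path
    search (bottleneck radius, length, curvature, cost and throughput), plus
    analysis of ligand passage along a detected tunnel by discretized,
    spatially restrained rigid-body pose optimization yielding per-slice
    energy profiles and barrier estimates. Includes alpha-sphere pocket
    detection for starting-point selection and a synthetic-structure module
    generating pseudo-proteins with analytically known channels for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
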