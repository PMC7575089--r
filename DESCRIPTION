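Package: clustlink
Title: Maximising Network Clustering by Link Addition, with Habitat-Network
    Robustness Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding where to add links to an undirected network so
    as to maximise its (Watts-Strogatz average) clustering coefficient: an
    exact incremental update of the clustering coefficient after a single link
    insertion, an exact single-link maximiser, Greedy and Lazy Greedy
    multi-link heuristics, an exhaustive enumeration oracle, and a uniform
    random baseline. Includes generators for standard network ensembles
    (random, regular, small-world; sparse and dense) and for synthetic
    landscape-based habitat networks (cost-raster landscapes with stream-bound
    habitat patches connected by least-cost paths), plus a stochastic
    patch-occupancy metapopulation simulation that quantifies how optimised
    link addition improves habitat-network robustness against random habitat
    loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite,
    optparse
Config/testthat/edition: 3
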