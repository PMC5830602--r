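Package: nestshore
Title: Morphodynamics, Spatial Eigenfunctions and Nestedness Analysis for
    Sandy-Beach Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for site-by-species analyses of sandy-beach
    macrobenthic metacommunities. Computes the Beach Index from grain size,
    tide range and slope, and classifies beaches along the
    reflective-intermediate-dissipative continuum; builds distance-based
    Moran eigenvector maps (dbMEM) from site coordinates with
    minimum-spanning-tree truncation; partitions community variation into
    pure environmental, shared, pure spatial and residual fractions via
    partial redundancy analysis on Hellinger-transformed abundances, with
    forward selection under a double stopping rule and permutation tests;
    ordinates communities by non-metric multidimensional scaling of
    Bray-Curtis dissimilarities and compares period configurations by
    Procrustes/PROTEST; and tests gradient-ordered nestedness (NODF and
    matrix temperature) against fixed-fixed null models sampled by the
    curveball algorithm, including a minimal site set-cover diagnostic for
    anti-nestedness. A seeded synthetic metacommunity generator with known
    environmental and spatial structure supports power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
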