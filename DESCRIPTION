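Package: morphnet
Title: Spatial Network Morphometrics of Radially Symmetric Particle Systems
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates two-dimensional systems of unit-diameter particles with
    radial symmetry (diffusion-limited and ballistic aggregates, Vicsek and
    Hexaflake fractals, Kagome and Hexagonal lattices), converts them into
    euclidean-threshold geometric graphs at a connectivity parameter r, and
    computes a spatial and topological metric panel: radius, radius of
    gyration, fractal dimension from radius-of-gyration scaling, the sixfold
    bond-orientational order parameter, degree statistics, clustering,
    shortest-path length, global efficiency, the center-perimeter
    communication ratio, and the efficiency cut-off of the connectivity
    parameter relative to a hexagonal-lattice baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
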