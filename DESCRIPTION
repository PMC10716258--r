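Package: vorocc
Title: Voronoi Diagram Density Estimation for Chromosome Conformation
    Capture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Adaptive density estimation for Hi-C and micro-C read pairs
    using Voronoi tessellation, in which the reciprocal area of each read
    pair's Voronoi cell is a local contact-density estimate. Provides
    reading and writing of the 4DN pairs format (plain text or BGZF) with
    a tile-based random-access index, interact-format contact lists,
    centroidal Voronoi smoothing by Lloyd iteration, identification of
    high-frequency contact bins from Voronoi densities via robust
    log-log distance-decay regression with one-sided z-tests and
    Benjamini-Hochberg false discovery rate control, observed/expected
    pileups with an average signal-enrichment statistic, a synthetic
    pairs-data generator with power-law distance decay, TAD blocks and
    planted focal loops, and publication-quality Voronoi, heatmap and
    triangle-view figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    interp,
    MASS,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    sp,
    Rsamtools,
    xml2,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
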