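Package: samsce
Title: Subcellular-Element Simulation of the Arabidopsis Shoot Apical Meristem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional and pseudo-three-dimensional (P3D) subcellular-element
    models of a longitudinal section of the Arabidopsis thaliana shoot apical
    meristem (SAM). Cells are closed rings of wall nodes enclosing cytoplasm
    nodes; nodes move by overdamped dynamics under soft-core Morse, linear-spring
    and bending-spring potentials. The package includes a turgor-pressure derived
    tunica boundary tension, exponential WUSCHEL/cytokinin signal gradients,
    signal-dependent growth and division with mechanically cued division planes,
    stochastic out-of-plane growth polarization (the P3D variant), a synthetic
    initial-tissue generator, snapshot input/output, and tissue-structure
    metrics: epidermal monolayer length, relative curvature, cell aspect ratio,
    percent-periclinal division frequency, and Voronoi adhesion-graph
    centralities (PageRank and randomized-shortest-path betweenness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
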