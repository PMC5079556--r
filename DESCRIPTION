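Package: firebreaks
Title: Centrality-Guided Placement of Fuel Breaks on Lattice Fire-Spread
    Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic cellular-automata simulation of wildland fire
    spread on heterogeneous landscapes, recast as a directed weighted
    lattice network whose edge weights are the cell-to-cell ignition
    probabilities.  Provides a synthetic artificial-forest generator,
    ESRI ASCII raster input for real landscapes (elevation, vegetation
    type and density), network centrality measures (betweenness,
    closeness, eigencentrality, Bonacich power centrality) on the
    fire-spread network, greedy fuel-break placement under a
    no-adjacent-removal constraint, and Monte-Carlo hazard-assessment
    campaigns: hazard-intensity curves R(d_f), strategy comparison with
    Welch t-tests, burning-frequency maps, and phase-transition
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
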