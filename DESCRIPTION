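Package: chromotrace
Title: Single-Nucleus Chromosome Walk Analysis and Integrative Modeling of
    Genomic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sequential super-resolution (single-molecule
    localization) imaging of megabase-scale chromosomal walks. Filters,
    merges, drift-corrects and clusters raw localizations; converts
    per-segment point clouds into Gaussian-smoothed 3D density maps with
    automatic iso-contour thresholds; computes distance, entanglement,
    surface-area, volume and sphericity statistics with power-law
    genomic-size correction, PCA-based compartment-state classification and
    homolog ellipticity tests; and fits Hi-C-derived bead-chain models into
    the density maps by rigid cross-correlation search followed by flexible
    simulated-annealing refinement under harmonic restraints (IMGR). A
    synthetic-data generator produces ground-truth chains, localization
    tables and contact matrices so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
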