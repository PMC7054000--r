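Package: cohesim
Title: Stochastic Loop-Extrusion Simulation and Chromatin Contact Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates cohesin-mediated chromatin loop extrusion on a 1D
    monomer lattice with oriented CTCF halting sites, stochastic pausing,
    dissociation and reloading, and converts extruder trajectories into
    Hi-C-like contact maps via an ideal-chain shortest-path approximation
    or a small bead-spring Langevin polymer model. Provides the companion
    analytics: contact-probability P(s) curves, cross-window insulation
    scores and boundary profiles, aggregate peak analysis (APA) of loops,
    TAD pileups, loop-length ECDFs, CTCF occupancy enrichment with
    translational controls, CTCF motif convergence classification, and
    union-merge interval overlaps. Also implements inverse-FRAP trace
    normalization with constrained single/bi-exponential residence-time
    fitting and model selection, and a synthetic-data generator for every
    input so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
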