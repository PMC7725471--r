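Package: vesiclehood
Title: Quantitative Morphometry of Dense-Core Vesicle Neighborhoods in
    Cryo-Electron Tomograms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies insulin secretory vesicles in cryo-electron
    tomograms of beta cells: per-vesicle size estimation from the central
    cross section (d = 2*sqrt(A/pi), V = pi*d^3/6), dense-core maturity
    classification from interior contrast, metal-cluster detection,
    assignment of tomograms to distance-defined subcellular regions
    (nuclear-membrane and plasma-membrane landmarks), and per-region
    neighborhood statistics (mature fraction, diameter distributions,
    count density, volume fraction) with Welch and Mann-Whitney region
    comparisons.  Includes a synthetic tomogram generator (vesicle fields
    in a lamella-thickness slab, membrane shells, dense cores, metal
    clusters, missing-wedge corruption, Gaussian noise) so that every
    stage of the pipeline is testable against known ground truth, plus a
    threshold-based 3D segmentation stand-in for manual annotation, and
    MRC-2014 volume input/output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
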