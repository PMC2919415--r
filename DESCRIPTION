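Package: ccstopo
Title: Topology Modelling of Protein Oligomers from Ion-Mobility Collision
    Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds low-resolution models of protein quaternary structure by
    combining incomplete atomic structures with collision cross-sections (CCS)
    measured by ion mobility-mass spectrometry.  Provides a seeded Monte-Carlo
    projection-approximation CCS calculator for atomic and sphere models,
    missing-mass accounting against full-length sequences, elastic-network
    domain decomposition and shape-based coarse-graining with radius
    calibration, density-based sizing and CCS-restrained placement of a sphere
    representing unresolved residues, archetypal oligomer generators (linear,
    ring, stacked, collapsed) with CCS-versus-stoichiometry trend lines,
    crystal-symmetry mining of candidate packings ranked by compactness, and a
    stepwise nested selection workflow that matches candidates to experimental
    CCS series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
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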