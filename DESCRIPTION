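Package: gmnet
Title: Single-Subject Grey-Matter Networks and Tau-PET Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts single-subject grey-matter similarity networks from
    3D grey-matter intensity volumes using 3x3x3-voxel cube nodes,
    rotation-maximised Pearson correlations and a permutation-calibrated
    binarisation threshold; computes global and regional graph-theory
    measures with small-world normalisation against degree-preserving
    random reference networks; builds Braak-stage tau-PET composite
    regions of interest including the temporal meta-ROI; and provides the
    covariate-adjusted association and bootstrap mediation analyses that
    relate tau burden to network topology and cognition. A seeded
    synthetic-cohort generator makes the full pipeline testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    RNifti,
    yaml,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
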