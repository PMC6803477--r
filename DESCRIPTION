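Package: cdrcanon
Title: Canonical Class Analysis and Prediction of Antigen Receptor CDR Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts complementarity-determining region (CDR) loops from
    IMGT-renumbered T-cell receptor and antibody structures with
    crystallographic quality filters, clusters loop backbones into canonical
    classes using a length-independent dynamic-time-warping distance with
    DBSCAN, names classes by the field convention, builds per-class
    position-specific scoring matrices for sequence-based canonical-form
    prediction with leave-one-out validation, and computes CDR3 torso
    geometry (pseudo bond and dihedral angles, loop anchor transform) and
    conformational-variability statistics. Includes a seed-deterministic
    synthetic loop generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
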