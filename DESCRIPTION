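Package: chlnet
Title: Chlorophyll Energy-Transfer Networks and Structural Comparison of
    Photosystem Supercomplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural-analysis toolkit for photosystem supercomplex
    coordinate models. Reads mmCIF/PDB files, classifies pigment, lipid and
    cluster cofactors through a configurable chemical-component map, and
    builds chlorophyll-to-chlorophyll Foerster resonance energy transfer
    (FRET) rate networks from the point-dipole approximation with the
    Qy transition dipole taken along the N-B to N-D pyrrole nitrogen axis.
    Also provides Kabsch rigid-body superposition, core-anchored
    antenna-subunit shift quantification, cross-structure cofactor
    site matching, and conserved-water-shell analysis around iron-sulfur
    clusters, plus a synthetic-structure generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
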