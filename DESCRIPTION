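Package: bandregion
Title: Band-Region Analysis of Lysine Accessibility in Cullin-RING
    Ligase Ubiquitination Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural modelling toolkit for predicting which surface
    lysines of a PROTAC-recruited target protein can be reached by the
    catalytic cysteine of the E2 enzyme docked on a Cullin-RING ligase.
    Provides PDB structure handling, rigid-body superposition and subunit
    grafting, anisotropic-network-model normal modes with mode animation,
    backbone dihedral sampling of the RBX1 hinge loop with synchronous
    rigid movement of the attached E2-ubiquitin module, steric clash
    filtering, distance-threshold accessibility classification ("band
    region" analysis), density-based triage of ternary docking poses, and
    synthetic ground-truth generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
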