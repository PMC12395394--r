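Package: excitissue
Title: Excitable Vertex-Model Dynamics in Epithelial Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vertex-model simulation of epithelial monolayers whose cell-cell
    junctions are mechanically excitable units: contractility activates upon
    stretch past a strain threshold, persists for a fixed period, and is
    followed by a refractory period, while junction rest lengths remodel
    viscoelastically. Builds periodic ordered (hexagonal) and disordered
    (Voronoi) tissues, integrates overdamped dynamics with T1 transitions,
    classifies quiescent, pulse and wave states, sweeps phase diagrams, and
    implements the one-dimensional three-junction effective theory with its
    closed-form propagation threshold and reactivation window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
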