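Package: rulenet
Title: Bipartite Species-Reaction Graphs for Rule-Based Models of Molecular Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, lays out, queries and renders directed bipartite
    species-reaction graphs from rule-based models of multi-component,
    multi-state molecular complexes. Models declare molecules with binding
    sites and tri-state ("on"/"off"/"don't care") state variables, complex
    species with curated complex instances, and categorized reaction rules
    (association, dissociation, transformation). The package provides a
    versioned JSON model format with validator, programmatic reference
    fixtures (a G-protein signaling model and an EGFR adaptor-binding
    model), force-directed, level-based and circular layouts with node
    overlap removal and layout persistence, name/molecule filtering and
    tri-state pattern search, and deterministic SVG, DOT and GraphML
    export with contact-map style glyph rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
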