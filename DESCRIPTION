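Package: fvscontrol
Title: Feedback Vertex Set Control of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Structural control of nonlinear gene regulatory network (GRN)
    dynamics via feedback vertex sets (FVS). Reads and writes signed directed
    networks (TSV edge lists, SIF, GraphML), enumerates all minimum feedback
    vertex sets exactly with an alternative-choice factorization, integrates
    decay-condition ordinary differential equation models with exact node
    clamping, finds and classifies steady states, verifies that clamping a
    full FVS (and only a full FVS) steers the system onto any chosen
    attractor, and performs exhaustive binary clamping scans over an FVS with
    tissue-marker readout classification. Ships toy fixtures and a synthetic
    stand-in for the ascidian (Ciona) cell-fate specification network, plus
    seeded generators for random signed digraphs and multistable dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
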