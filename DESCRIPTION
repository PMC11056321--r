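Package: gted
Title: Graph Traversal Edit Distance for Edge-Labeled Eulerian Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and lower-bound computation of the graph traversal edit
    distance (GTED) between unidirectional, edge-labeled Eulerian graphs such
    as de Bruijn graphs built from nucleotide sequences. Implements the
    alignment (product) graph construction with source/sink augmentation, an
    exact integer linear program solved by iterative strongly-connected-
    component constraint generation, a compact ordering-variable (MTZ-style)
    formulation, the flow-projection lower bound and its interpretation as the
    closed-trail cover traversal edit distance (CCTED) with decoding of optimal
    solutions into matched closed-trail covers, a boundary-matrix (2-simplex)
    formulation for cross-validation, brute-force oracles for small instances,
    and deterministic generators for benchmark instance families including a
    Hamiltonian-path reduction. Models are solved with the HiGHS solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
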