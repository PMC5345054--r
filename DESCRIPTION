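Package: rcc5align
Title: RCC-5 Taxonomic Concept Alignment and Merging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-taxonomy alignment of taxonomic concepts under the
    Region Connection Calculus with five base relations (RCC-5).
    Reads and writes Euler/X-dialect alignment inputs, decides logical
    consistency of expert articulations over 2-5 classification
    hierarchies via a finite place-occupancy model, computes Maximally
    Informative Relations (MIR) for every cross-taxonomy concept pair,
    enumerates possible worlds, and builds merged congruence graphs
    with inferred proper-inclusion and overlap edges, including
    relaxation of the parent-coverage constraint for undersampled
    concepts. Also provides a cladistic character-matrix layer
    (NONA/Hennig86-style and TSV input, coded-coverage statistics,
    diagnostic character-state combination queries, morphometric ratio
    checks) and a seeded synthetic-world generator with known
    ground-truth relations for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
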