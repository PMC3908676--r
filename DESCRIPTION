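Package: robcomplex
Title: Robustness-Based Detection of Overlapping Protein Complexes in PPI Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects overlapping protein complexes in protein-protein
    interaction (PPI) networks by greedy seed expansion constrained by a
    cluster robustness degree and a minimum Jaccard edge weight, with
    neighbour-affinity based post-merging. Includes the standard
    complex-evaluation metrics (neighbour-affinity matched precision, recall
    and F-measure, co-localization score, Gene Ontology semantic similarity
    aggregation), readers and writers for edge-list/SIF networks and
    MCL-style complex files, a deterministic planted-complex network
    generator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
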