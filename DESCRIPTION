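Package: csrwalign
Title: Multiple Network Alignment via Context-Sensitive Random Walks
Version: 0.1.0
Authors@R:
    person("CSRW", "Maintainers", email = "maintainers@csrwalign.example.org",
           role = c("aut", "cre"))
Description: Global multiple alignment of protein-protein interaction
    networks. Node correspondence between each pair of networks is scored
    by the stationary distribution of a context-sensitive random walk with
    restart on the reduced product graph of similar node pairs, blended
    with normalized node similarity. Scores are optionally refined by a
    probabilistic consistency transformation and turned into many-to-many
    equivalence classes by a greedy maximum-expected-accuracy procedure.
    Includes alignment quality metrics (correct nodes, specificity, mean
    normalized entropy, conserved interactions, coverage), plain-text
    readers and writers for edge lists, similarity tables, annotations and
    alignments, and a duplication-model benchmark generator for testing
    aligners without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
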