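Package: hourglassNet
Title: Weighted Hourglass Analysis of Directed Source-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the hourglass (bow-tie) architecture of directed
    dependency networks whose nodes act as sources, intermediates or
    targets, such as the C. elegans chemical-synapse connectome with
    sensory, inter- and motor neurons.  Enumerates bounded-length
    source-target paths, assigns path weights under pluggable schemes
    including the multi-edge transformation (product of synapse counts),
    computes weighted path centrality and the greedy tau-core (the
    hourglass "waist"), derives the flat dependency network and the
    H-score, and assesses significance with edge-shuffling and
    edge-weight-permutation null models.  Includes seeded generators for
    layered synthetic networks with a controllable waist.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
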