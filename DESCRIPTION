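Package: persona2vec
Title: Multi-Role Node Embeddings via Ego-Splitting Persona Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns multiple vector representations per node in a graph by
    splitting nodes into role-specific persona nodes. Each node's ego-network
    is clustered locally; one persona is created per local cluster, personas
    inherit the original edges of their cluster and are tied together by
    weighted directed persona edges so the persona graph stays connected.
    The persona graph is embedded with random-walk skip-gram (negative
    sampling or hierarchical softmax), fine-tuning a base embedding of the
    original graph. Includes a connectivity-preserving link-prediction
    benchmark harness, a planted overlapping-community graph generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
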