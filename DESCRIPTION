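Package: sfcnlp
Title: Link Prediction with Similarity-Based Future Common Neighbors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Similarity-based link prediction for undirected simple
    networks.  Implements eight classical common-neighbor similarity
    indexes (CN, Salton, RA, HPI, HDI, LHN, LNBRA, LP) and the
    similarity-based future common neighbors (SFCN) model, which scores a
    node pair by combining its current common neighbors with three classes
    of nodes predicted to become common neighbors as the network evolves.
    Includes train/probe edge splitting, exact and sampled AUC,
    precision at L, replicated experiments, parameter-grid and
    training-ratio sweeps, edge-list input/output, descriptive network
    statistics, seeded synthetic-graph generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
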