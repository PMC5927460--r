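Package: napr
Title: Network Annotation Propagation for Molecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Re-ranks in silico fragmentation candidate structures for the
    nodes of an MS/MS molecular network by propagating structural information
    along cosine-weighted edges. Implements network Fusion scoring (sigmoid
    combination of the base in silico score with Tanimoto similarity to
    spectral-library structures on neighboring nodes), network Consensus
    scoring (the same combination against the top-ranked candidates of each
    neighbor), chained Fusion-then-Consensus propagation, unsupervised
    clustering of candidate structures (Tanimoto dissimilarity, metric
    multidimensional scaling, Ward linkage and an adaptive dynamic branch
    cut) with substructure-level concordance metrics, dense-rank evaluation
    with a uniform random baseline, and a seeded synthetic-network generator
    for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
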