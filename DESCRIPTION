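Package: foldsearch
Title: Invariant Graph-Network Embedding and Search for Protein Domain
    Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Embedding-based similarity search for protein domain
    structures. A stack of distance-based graph message-passing blocks
    (an E(n)-invariant graph network without coordinate updates) maps a
    domain's C-alpha trace to a fixed-size embedding; the network is
    trained as a CATH-style hierarchical fold classifier with
    reciprocal-frequency class weights and coordinate-noise
    augmentation. Databases of domain embeddings support exhaustive
    top-k cosine retrieval, with candidate hits validated by a built-in
    C-alpha TM-score aligner (Kabsch superposition plus iterative
    dynamic programming). A multi-domain search matches every domain of
    a query chain against database chains, enumerates injective
    query-hit domain pairings above a TM-score threshold, and classifies
    each hit chain as an unordered, discontiguous, contiguous, or exact
    multi-domain-architecture match. Includes a pluggable chain
    segmentation contract and a synthetic-structure generator so that
    training, search, and classification are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
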