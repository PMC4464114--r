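Package: hpaaphylo
Title: Homopolymeric Amino-Acid Tracts, Exhaustive Topology Testing and
    Gene-Duplication Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify homopolymeric amino-acid (HPAA) tracts in
    proteomes, evaluate all candidate gene-family topologies by maximum
    likelihood with RELL bootstrap and Kishino-Hasegawa/Shimodaira-Hasegawa
    tests, count gene duplications relative to a species split by
    probabilistic (bootstrap-weighted) gene-tree/species-tree
    reconciliation, and probe the sensitivity of these inferences to
    alignment and trimming choices when convergent HPAA tracts are present.
    Includes a synthetic-data generator producing proteomes with controlled
    tract statistics and gene families simulated under alternative
    duplication-timing scenarios with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
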