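Package: lsgclust
Title: Chromosomal Clustering and Expression States of Lineage-Specific Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of lineage-specific gene (LSG)
    clusters along chromosomes and of their expression behavior. Provides
    phylostratum assignment from homology hit tables, max-gap cluster
    detection with chromosome-stratified permutation significance,
    window-free model-averaged (BIC-weighted Bernoulli segmentation)
    clustering profiles with 95% model-uncertainty envelopes, relative
    expression normalized to the lowest condition with Gamma-Poisson
    credible intervals, contingency (chi-square) enrichment of gene classes
    across expression states with Benjamini-Hochberg adjustment, pairwise
    co-expression coordination within clusters, and seeded simulators for
    genomes, homology hits, and replicated count matrices so the whole
    chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
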