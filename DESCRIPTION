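Package: famcontext
Title: Comparative Genomics of Protein Superfamilies: Membrane Propensity,
    Phyletic Metrics, Similarity Networks and Gene-Context Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing a protein domain superfamily across
    genomes. Scores sequences with a transmembrane-tendency hydropathy scale
    and compares family score distributions (Kruskal-Wallis, Dunn's post-hoc
    test with Bonferroni correction, critical-difference grouping); computes
    phyletic spread and depth (mediant) metrics from lineage presence counts;
    builds weighted family-relationship networks from profile-profile
    comparison p-values and detects sub-networks with the Leiden algorithm;
    decomposes domain architectures and gene neighborhoods into a
    domain-adjacency graph, merges cliques around a focal domain into its
    dense subgraph, and tests functional-category enrichment with Fisher's
    exact test under Benjamini-Hochberg correction. Includes a seeded
    synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings,
    rtracklayer,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
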