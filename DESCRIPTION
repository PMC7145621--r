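Package: pangraphr
Title: Partitioned Pangenome Graphs, Species Clustering and Regions of
    Genomic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative pangenomics toolkit for prokaryotic genomes:
    MinHash sketching and Mash-style genome distances, quality-filtered
    species clustering by Louvain community detection on the thresholded
    distance graph, homologous protein families by 80/80
    identity-coverage single-linkage clustering, partitioned pangenome
    graphs (persistent/shell/cloud) fitted with a multivariate Bernoulli
    mixture model smoothed by a Markov random field, and score-based
    detection of regions of genomic plasticity projected onto individual
    genomes.  Includes a seeded synthetic-data generator with known truth
    (species labels, family membership, partition labels, planted
    islands) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringi,
    rlang,
    ggplot2,
    generics,
    igraph,
    ape,
    jsonlite,
    withr,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
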