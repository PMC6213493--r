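Package: geneGangs
Title: Detection of Conserved Collinear Gene Neighborhoods (Gene Gangs) in
    Sets of Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects "gene gangs": groups of three or more monocistronic
    genes that remain physically co-localized across (nearly) all genomes
    of a set, irrespective of gene order, strand or intervening genes.
    Implements the full discovery pipeline for sets of annotated viral
    genomes with precomputed homology clusters: seed-cluster classification,
    genomic groupings under a center-to-center collinearity window,
    cluster-gang formation, prevalence filtering, merging to disjoint gene
    gangs, paralog correction, ruliness computation and filtering. Also
    provides the single-copy core gene (SCCG) pairwise distance-conservation
    analyses (strictly constrained bins and growing bins), an empirical-CDF
    random-shuffle null model with half-maximal detectability thresholds,
    patristic distances from a phylogeny, per-gang topology metrics
    (ruliness, synteny, strandedness, alien-gene infiltration), and a
    synthetic genome simulator with planted gangs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
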