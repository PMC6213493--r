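# Fixture builders used across the suite. All coordinates 1-based
# inclusive; quickGenome places fixed-width genes at given centers so
# center-to-center distances are exact by construction.

quickGenome <- function(id, centers, clusters = NULL, strands = NULL,
                        contig = "chr", halfWidth = 100) {
  n <- length(centers)
  if (is.null(clusters)) clusters <- rep(NA_character_, n)
  if (is.null(strands)) strands <- rep("+", n)
  contig <- rep(contig, length.out = n)
  ft <- data.frame(
    feature_id = sprintf("%s_f%02d", id, seq_len(n)),
    contig_id = contig,
    start = centers - halfWidth, end = centers + halfWidth,
    strand = strands, cluster_id = clusters, product = NA_character_,
    stringsAsFactors = FALSE)
  ctgs <- data.frame(contig_id = unique(contig),
                     length = max(centers) + halfWidth + 1000)
  AnnotatedGenome(id, features = ft, contigs = ctgs)
}

# A ClusterGang built directly from a per-genome feature table; the table
# needs genome_id, feature_id, cluster_id, center columns.
quickClusterGang <- function(seed, tab, halfWidth = 100) {
  tab$contig_id <- if (is.null(tab$contig_id)) "chr" else tab$contig_id
  tab$start <- tab$center - halfWidth
  tab$end <- tab$center + halfWidth
  tab$strand <- if (is.null(tab$strand)) "+" else tab$strand
  tab$product <- NA_character_
  tab$is_seed <- tab$cluster_id == seed
  cols <- c("genome_id", "feature_id", "contig_id", "start", "end",
            "strand", "cluster_id", "product", "is_seed")
  new("ClusterGang", seedCluster = seed, features = tab[, cols])
}

# A finalized GeneGang straight from a member table (bypassing detection),
# for testing ruliness / reporting operations in isolation.
quickGeneGang <- function(id, tab, nGenomes, halfWidth = 100) {
  tab$contig_id <- if (is.null(tab$contig_id)) "chr" else tab$contig_id
  if (is.null(tab$start)) {
    tab$start <- tab$center - halfWidth
    tab$end <- tab$center + halfWidth
  }
  tab$strand <- if (is.null(tab$strand)) "+" else tab$strand
  tab$product <- NA_character_
  tab$is_seed <- TRUE
  cols <- c("genome_id", "feature_id", "contig_id", "start", "end",
            "strand", "cluster_id", "product", "is_seed")
  cl <- sort(unique(tab$cluster_id[!is.na(tab$cluster_id)]))
  new("GeneGang", gangId = id, clusterIds = cl, features = tab[, cols],
      ruliness = numeric(), nGenomes = as.integer(nGenomes),
      flags = character())
}

# GenomeSet where one cluster occurs at a fixed center in a given number
# of genomes; used for prevalence-threshold tests.
prevalenceSet <- function(nGenomes, clusterCenters, presentIn) {
  genomes <- lapply(seq_len(nGenomes), function(k) {
    id <- sprintf("g%02d", k)
    keep <- vapply(names(clusterCenters), function(cl)
      k <= presentIn[[cl]], logical(1))
    cls <- names(clusterCenters)[keep]
    if (!length(cls))
      return(AnnotatedGenome(id, contigs = data.frame(contig_id = "chr",
                                                      length = 1e6)))
    g <- quickGenome(id, centers = unname(unlist(clusterCenters[cls])),
                     clusters = cls)
    g
  })
  GenomeSet(genomes)
}

# Canonical signature of a list of gangs: sorted cluster-id strings.
gangSignatures <- function(gangs) {
  sort(vapply(gangs, function(g) paste(sort(clusterIds(g)), collapse = ","),
              character(1)))
}
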