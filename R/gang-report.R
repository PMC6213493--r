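## Per-genome left-to-right order of gang cluster ids (duplicates collapsed
## to first occurrence). Returns list of character vectors, one per genome
## that has >= 1 member feature.
.gangOrders <- function(gang) {
  tab <- gang@features
  tab <- tab[!is.na(tab$cluster_id) & tab$cluster_id %in% gang@clusterIds, ,
             drop = FALSE]
  tab <- tab[order(tab$genome_id, tab$contig_id, tab$start), , drop = FALSE]
  lapply(split(tab, tab$genome_id), function(sub)
    sub$cluster_id[!duplicated(sub$cluster_id)])
}

## Strand of the first occurrence of each cluster, aligned with .gangOrders.
.gangStrands <- function(gang) {
  tab <- gang@features
  tab <- tab[!is.na(tab$cluster_id) & tab$cluster_id %in% gang@clusterIds, ,
             drop = FALSE]
  tab <- tab[order(tab$genome_id, tab$contig_id, tab$start), , drop = FALSE]
  lapply(split(tab, tab$genome_id), function(sub) {
    first <- !duplicated(sub$cluster_id)
    stats::setNames(sub$strand[first], sub$cluster_id[first])
  })
}

#' Consensus left-to-right order of a gang's cluster ids
#'
#' The most frequent order of the gang cluster ids across genomes, with an
#' order and its full reversal counted as the same arrangement. Ties are
#' broken lexicographically; duplicated clusters collapse to their first
#' occurrence.
#'
#' @param gang a finalized [GeneGang-class].
#' @return character vector of cluster ids in consensus order.
#' @export
consensusOrder <- function(gang) {
  ords <- .gangOrders(gang)
  if (!length(ords)) return(character())
  keys <- vapply(ords, function(o) {
    f <- paste(o, collapse = "|"); r <- paste(rev(o), collapse = "|")
    if (f <= r) f else r
  }, character(1))
  cnt <- sort(table(keys), decreasing = TRUE)
  top <- names(cnt)[cnt == max(cnt)]
  modal <- sort(top)[1L]
  ## representative orientation: most frequent observed orientation of the
  ## modal arrangement, ties lexicographic
  obs <- vapply(ords[keys == modal], paste, character(1), collapse = "|")
  ocnt <- sort(table(obs), decreasing = TRUE)
  best <- sort(names(ocnt)[ocnt == max(ocnt)])[1L]
  strsplit(best, "|", fixed = TRUE)[[1L]]
}

#' Topology metrics of a gene gang
#'
#' Reports, per gang: the maximum and modal (consensus) per-genome member
#' count; the number of genomes that are ruly (contain every gang cluster
#' id), that maintain synteny (their order of gang clusters matches the
#' consensus order, or its full reversal, restricted to the clusters they
#' carry), that conserve strandedness (strand pattern matches the
#' consensus pattern or its global inversion; evaluated among syntenic
#' genomes, a genome-wide reversal flips both order and strands), and that
#' are infiltrated by alien genes (at least one feature lacking a gang
#' cluster id lies between the outermost gang members). Genomes without
#' any member feature are excluded from the denominators.
#'
#' @param gang a finalized [GeneGang-class].
#' @param gs the parent [GenomeSet-class].
#' @return list with `gang_id`, `max_members`, `consensus_members`,
#'   `n_ruly_genomes`, `n_syntenic_genomes`,
#'   `n_strand_conserved_genomes`, `n_infiltrated_genomes`,
#'   `n_genomes_present`.
#' @export
topologyMetrics <- function(gang, gs) {
  tab <- gang@features
  perGenome <- split(tab, tab$genome_id)
  counts <- vapply(perGenome, nrow, integer(1))
  maxMembers <- max(counts)
  tc <- table(counts)
  consensusMembers <- min(as.integer(names(tc)[tc == max(tc)]))

  ords <- .gangOrders(gang)
  strands <- .gangStrands(gang)
  nRuly <- sum(vapply(ords, function(o)
    all(gang@clusterIds %in% o), logical(1)))

  cons <- consensusOrder(gang)
  synOK <- vapply(names(ords), function(g) {
    o <- ords[[g]]
    cr <- cons[cons %in% o]
    length(o) == length(cr) && all(o %in% cr) &&
      (identical(o, cr) || identical(o, rev(cr)))
  }, logical(1))

  ## normalized strand pattern: reversed genomes are flipped back
  normStrand <- lapply(names(ords)[synOK], function(g) {
    o <- ords[[g]]
    cr <- cons[cons %in% o]
    s <- strands[[g]][o]
    if (!identical(o, cr)) {            # matched as the reversal
      s <- rev(ifelse(s == "+", "-", "+"))
      names(s) <- rev(o)
    }
    s
  })
  names(normStrand) <- names(ords)[synOK]
  consStrand <- if (length(normStrand)) {
    allCl <- unique(unlist(lapply(normStrand, names)))
    vapply(allCl, function(cl) {
      v <- unlist(lapply(normStrand, function(s) s[cl]))
      v <- v[!is.na(v)]
      tt <- sort(table(v), decreasing = TRUE)
      sort(names(tt)[tt == max(tt)])[1L]
    }, character(1))
  } else character()
  strandOK <- vapply(names(ords), function(g) {
    if (!isTRUE(synOK[[g]])) return(FALSE)
    s <- normStrand[[g]]
    ref <- consStrand[names(s)]
    identical(unname(s), unname(ref)) ||
      identical(unname(s), unname(ifelse(ref == "+", "-", "+")))
  }, logical(1))

  infiltrated <- vapply(names(perGenome), function(gid) {
    mem <- perGenome[[gid]]
    ft <- gs@genomes[[gid]]@features
    for (ctg in unique(mem$contig_id)) {
      m <- mem[mem$contig_id == ctg, , drop = FALSE]
      if (nrow(m) < 2L) next
      cen <- (m$start + m$end) / 2
      lo <- min(cen); hi <- max(cen)
      sub <- ft[ft$contig_id == ctg, , drop = FALSE]
      c2 <- (sub$start + sub$end) / 2
      alien <- (is.na(sub$cluster_id) |
                  !(sub$cluster_id %in% gang@clusterIds)) &
        c2 > lo & c2 < hi
      if (any(alien)) return(TRUE)
    }
    FALSE
  }, logical(1))

  list(gang_id = gang@gangId,
       max_members = maxMembers,
       consensus_members = consensusMembers,
       n_ruly_genomes = nRuly,
       n_syntenic_genomes = sum(synOK),
       n_strand_conserved_genomes = sum(strandOK),
       n_infiltrated_genomes = sum(infiltrated),
       n_genomes_present = length(perGenome))
}

#' Table of topology metrics for a list of gangs
#'
#' One row per gang, shaped like a conservation summary table: member
#' counts, ruly/syntenic/strand-conserved/infiltrated genome counts.
#'
#' @param gangs list of [GeneGang-class] objects.
#' @param gs the parent [GenomeSet-class].
#' @return `data.frame`, one row per gang.
#' @export
topologyTable <- function(gangs, gs) {
  rows <- lapply(gangs, function(g)
    as.data.frame(topologyMetrics(g, gs), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gang_id = character(), max_members = integer(),
                      consensus_members = integer(),
                      n_ruly_genomes = integer(),
                      n_syntenic_genomes = integer(),
                      n_strand_conserved_genomes = integer(),
                      n_infiltrated_genomes = integer(),
                      n_genomes_present = integer())
  rownames(out) <- NULL
  out
}

#' Cluster-based dot-plot data for a genome pair
#'
#' One point per pair of features sharing a homology cluster: the feature
#' centers in each genome plus whether the strands agree. Identical
#' genomes give a diagonal; inverted blocks give anti-diagonal segments
#' with `same_strand = FALSE`; paralogs give off-diagonal points.
#'
#' @param ga,gb [AnnotatedGenome-class] objects.
#' @return `data.frame` with `cluster_id`, `feature_a`, `feature_b`,
#'   `center_a`, `center_b`, `contig_a`, `contig_b`, `same_strand`.
#' @export
dotPlotData <- function(ga, gb) {
  fa <- ga@features; fb <- gb@features
  fa <- fa[!is.na(fa$cluster_id), , drop = FALSE]
  fb <- fb[!is.na(fb$cluster_id), , drop = FALSE]
  shared <- intersect(fa$cluster_id, fb$cluster_id)
  parts <- lapply(shared, function(cl) {
    a <- fa[fa$cluster_id == cl, , drop = FALSE]
    b <- fb[fb$cluster_id == cl, , drop = FALSE]
    idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(cluster_id = cl,
               feature_a = a$feature_id[idx$i],
               feature_b = b$feature_id[idx$j],
               center_a = (a$start[idx$i] + a$end[idx$i]) / 2,
               center_b = (b$start[idx$j] + b$end[idx$j]) / 2,
               contig_a = a$contig_id[idx$i],
               contig_b = b$contig_id[idx$j],
               same_strand = a$strand[idx$i] == b$strand[idx$j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(cluster_id = character(), feature_a = character(),
                      feature_b = character(), center_a = numeric(),
                      center_b = numeric(), contig_a = character(),
                      contig_b = character(), same_strand = logical())
  rownames(out) <- NULL
  out
}

#' Export gang-annotated gene tracks and homology connectors
#'
#' Plot-ready tables for a gang alignment figure: a per-genome gene track
#' (every feature, tagged with its gang id or `NA`) and connector lines
#' joining features of the same homology cluster between consecutive
#' genomes of the set.
#'
#' @param gs a [GenomeSet-class].
#' @param gangs list of finalized [GeneGang-class] objects.
#' @return list of two `data.frame`s: `tracks` and `connectors`.
#' @export
exportGangAlignment <- function(gs, gangs) {
  ft <- features(gs)
  ft$center <- (ft$start + ft$end) / 2
  gangOf <- character(0)
  for (g in gangs) {
    key <- paste(g@features$genome_id, g@features$feature_id, sep = "\r")
    gangOf[key] <- g@gangId
  }
  key <- paste(ft$genome_id, ft$feature_id, sep = "\r")
  ft$gang_id <- unname(gangOf[key])
  tracks <- ft

  ids <- genomeIds(gs)
  conns <- list()
  if (length(ids) >= 2L) {
    for (k in seq_len(length(ids) - 1L)) {
      dp <- dotPlotData(gs@genomes[[ids[k]]], gs@genomes[[ids[k + 1L]]])
      if (nrow(dp))
        conns[[k]] <- cbind(genome_a = ids[k], genome_b = ids[k + 1L], dp,
                            stringsAsFactors = FALSE)
    }
  }
  connectors <- do.call(rbind, conns)
  if (is.null(connectors))
    connectors <- data.frame(genome_a = character(), genome_b = character())
  rownames(connectors) <- NULL
  list(tracks = tracks, connectors = connectors)
}

#' Write gang results to a directory
#'
#' Writes `gangs.json` (full structure: gang, clusters, ruliness, member
#' features per genome), `gangs.tsv` (one row per member feature),
#' `topology.tsv` (one row per gang) and `gang_members.gff3` (member
#' features of all gangs with gang ids as attributes, one file for the
#' whole set using genome-qualified contig names).
#'
#' @param gangs list of [GeneGang-class] objects.
#' @param gs the parent [GenomeSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGangTables <- function(gangs, gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jj <- lapply(gangs, function(g) list(
    gang_id = g@gangId,
    cluster_ids = g@clusterIds,
    ruliness = as.list(g@ruliness),
    gang_ruliness = if (length(g@ruliness)) min(g@ruliness) else NA,
    flags = g@flags,
    features = g@features))
  jsonlite::write_json(jj, file.path(dir, "gangs.json"), auto_unbox = TRUE,
                       digits = NA)
  tsv <- do.call(rbind, lapply(gangs, function(g)
    cbind(gang_id = g@gangId, g@features, stringsAsFactors = FALSE)))
  if (is.null(tsv)) tsv <- data.frame(gang_id = character())
  utils::write.table(tsv, file.path(dir, "gangs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(topologyTable(gangs, gs),
                     file.path(dir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(tsv)) {
    gr <- GenomicRanges::GRanges(
      seqnames = paste(tsv$genome_id, tsv$contig_id, sep = ":"),
      ranges = IRanges::IRanges(tsv$start, tsv$end),
      strand = tsv$strand)
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- paste(tsv$genome_id, tsv$feature_id, sep = ":")
    gr$gang_id <- tsv$gang_id
    gr$cluster_id <- tsv$cluster_id
    rtracklayer::export(gr, file.path(dir, "gang_members.gff3"),
                        format = "gff3")
  }
  invisible(dir)
}
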