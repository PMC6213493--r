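#' Read an annotated genome from GFF3 + FASTA
#'
#' Uses the GFF3 and FASTA parsers from rtracklayer/Biostrings. CDS (or,
#' where a record has no CDS children, `gene`) features become
#' [AnnotatedGenome-class] features; GFF3 coordinates are 1-based inclusive and are
#' used as-is. Contig lengths come from the FASTA.
#'
#' @param gffPath path to a GFF3 file.
#' @param fastaPath path to the matching FASTA of contig sequences.
#' @param genomeId genome identifier; defaults to the GFF3 file stem.
#' @return a [AnnotatedGenome-class].
#' @export
readGFF3Genome <- function(gffPath, fastaPath, genomeId = NULL) {
  if (is.null(genomeId))
    genomeId <- sub("\\.(gff3?|gff)$", "", basename(gffPath))
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ct <- data.frame(contig_id = names(seqs),
                   length = as.numeric(Biostrings::width(seqs)),
                   stringsAsFactors = FALSE)

  gr <- rtracklayer::import(gffPath, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    pick <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(NA_character_, length(gr))
    fid <- pick("ID")
    if (anyNA(fid)) {
      alt <- pick("Name")
      fid[is.na(fid)] <- alt[is.na(fid)]
    }
    fid[is.na(fid)] <- sprintf("%s_F%04d", genomeId, which(is.na(fid)))
    ft <- data.frame(
      feature_id = fid,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      cluster_id = pick("cluster_id"),
      product = pick("product"),
      stringsAsFactors = FALSE)
    ft$strand[!ft$strand %in% c("+", "-")] <- "+"
    bad <- setdiff(unique(ft$contig_id), ct$contig_id)
    if (length(bad))
      .stopf("GFF3 references contig(s) absent from FASTA: %s",
             paste(bad, collapse = ", "))
  } else {
    ft <- .emptyFeatureTable()
  }
  AnnotatedGenome(genomeId, features = ft, contigs = ct)
}

#' Write a genome's features to GFF3 (and optionally its contigs to FASTA)
#'
#' The inverse of [readGFF3Genome()]: re-reading the written pair
#' reproduces identical `(feature_id, start, end, strand)` tuples.
#' Cluster assignments ride along as a `cluster_id` attribute.
#'
#' @param genome a [AnnotatedGenome-class].
#' @param gffPath output GFF3 path.
#' @param fastaPath optional output FASTA path; contig sequences are
#'   emitted as runs of `N` of the right length (this package never
#'   interprets sequence content).
#' @return `gffPath`, invisibly.
#' @export
writeGFF3Genome <- function(genome, gffPath, fastaPath = NULL) {
  ft <- genome@features
  seqlens <- stats::setNames(genome@contigs$length, genome@contigs$contig_id)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(ft$contig_id, levels = names(seqlens)),
    ranges = IRanges::IRanges(start = ft$start, end = ft$end),
    strand = if (nrow(ft)) ft$strand else character(),
    seqlengths = seqlens)
  gr$type <- rep("CDS", length(gr))
  gr$phase <- rep(0L, length(gr))
  gr$ID <- ft$feature_id
  gr$cluster_id <- ft$cluster_id
  gr$product <- ft$product
  rtracklayer::export(gr, gffPath, format = "gff3")
  if (!is.null(fastaPath)) {
    seqs <- Biostrings::DNAStringSet(vapply(
      genome@contigs$length,
      function(n) paste(rep("N", n), collapse = ""), character(1)))
    names(seqs) <- genome@contigs$contig_id
    Biostrings::writeXStringSet(seqs, fastaPath)
  }
  invisible(gffPath)
}

#' Attach homology-cluster assignments from a table
#'
#' Reads a tab-separated table with columns `genome_id`, `feature_id`,
#' `cluster_id` (header optional, `#` comments allowed) and attaches the
#' cluster ids to matching features of the set. Features absent from the
#' table keep `cluster_id = NA`. Rows referencing unknown features are
#' skipped with a warning; duplicate `(genome_id, feature_id)` rows with
#' conflicting cluster ids are an error.
#'
#' @param path path to the TSV (or a `data.frame` with the three columns).
#' @param gs a [GenomeSet-class].
#' @return the [GenomeSet-class] with cluster ids attached.
#' @export
readClusterTable <- function(path, gs) {
  if (is.data.frame(path)) {
    tab <- path
    names(tab)[1:3] <- c("genome_id", "feature_id", "cluster_id")
  } else {
    if (!file.exists(path)) .stopf("cannot read cluster table '%s'", path)
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw)) & !grepl("^#", raw)]
    if (!length(raw)) {
      tab <- data.frame(genome_id = character(), feature_id = character(),
                        cluster_id = character())
    } else {
      first <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
      hasHeader <- identical(tolower(first[1:3]),
                             c("genome_id", "feature_id", "cluster_id"))
      tab <- utils::read.table(text = raw, sep = "\t", header = hasHeader,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
      names(tab)[1:3] <- c("genome_id", "feature_id", "cluster_id")
    }
  }
  tab$genome_id <- as.character(tab$genome_id)
  tab$feature_id <- as.character(tab$feature_id)
  tab$cluster_id <- as.character(tab$cluster_id)

  key <- paste(tab$genome_id, tab$feature_id, sep = "\r")
  if (anyDuplicated(key)) {
    per <- split(tab$cluster_id, key)
    bad <- names(per)[vapply(per, function(v) length(unique(v)) > 1L,
                             logical(1))]
    if (length(bad))
      .stopf("conflicting cluster assignments for %d feature(s), e.g. '%s'",
             length(bad), gsub("\r", "/", bad[1L]))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }

  nSkipped <- 0L
  newGenomes <- lapply(gs@genomes, function(g) {
    here <- tab[tab$genome_id == g@genomeId, , drop = FALSE]
    i <- match(g@features$feature_id, here$feature_id)
    g@features$cluster_id <- ifelse(is.na(i), NA_character_,
                                    here$cluster_id[i])
    g
  })
  known <- unlist(lapply(gs@genomes, function(g)
    paste(g@genomeId, g@features$feature_id, sep = "\r")), use.names = FALSE)
  nSkipped <- sum(!paste(tab$genome_id, tab$feature_id, sep = "\r") %in% known)
  if (nSkipped > 0L)
    .warnf("%d cluster-table row(s) reference unknown features; skipped",
           nSkipped)
  GenomeSet(newGenomes)
}

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that additionally insists on
#' branch lengths, without which patristic distances are undefined.
#'
#' @param path path to a Newick file (or a Newick string).
#' @return an [ape::phylo] object.
#' @export
readNewick <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path) else
    ape::read.tree(text = path)
  if (is.null(tree)) .stopf("could not parse Newick from '%s'", path)
  if (is.null(tree$edge.length))
    .stopf("phylogeny has no branch lengths; patristic distances undefined")
  tree
}
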