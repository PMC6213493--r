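#' Read an annotated genome from a GenBank flat file
#'
#' Minimal reader for GenBank flat files with CDS features: one
#' [AnnotatedGenome-class] feature per CDS. Multi-record files are read as multiple
#' contigs of the same genome. The feature id is taken from the
#' `locus_tag` qualifier, falling back to `protein_id` and finally to a
#' synthesized ordinal id; the product string is kept when present. A CDS
#' with a `join()` (or `order()`) location is collapsed to its outermost
#' span with a warning, since all downstream analyses work on gene centers.
#'
#' @param path path to a GenBank flat file.
#' @param genomeId genome identifier; defaults to the first record's LOCUS
#'   name.
#' @return a [AnnotatedGenome-class].
#' @export
readGenBank <- function(path, genomeId = NULL) {
  if (!file.exists(path)) .stopf("cannot read GenBank file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    .stopf("'%s' does not look like a GenBank flat file (no LOCUS line)", path)

  recStarts <- grep("^LOCUS", lines)
  recEnds <- c(recStarts[-1L] - 1L, length(lines))
  feats <- list()
  contigs <- list()
  nJoin <- 0L

  for (r in seq_along(recStarts)) {
    rec <- lines[recStarts[r]:recEnds[r]]
    locus <- strsplit(trimws(rec[1L]), "\\s+")[[1L]]
    contigId <- locus[2L]
    contigLen <- suppressWarnings(as.numeric(locus[3L]))
    if (is.null(genomeId)) genomeId <- contigId

    fStart <- grep("^FEATURES", rec)
    if (!length(fStart)) {
      contigs[[r]] <- data.frame(contig_id = contigId, length = contigLen)
      next
    }
    fEnd <- grep("^(ORIGIN|CONTIG|//)", rec)
    fEnd <- if (length(fEnd)) min(fEnd[fEnd > fStart[1L]]) - 1L else length(rec)
    body <- rec[(fStart[1L] + 1L):fEnd]

    ## glue continuation lines (21 leading spaces) onto their feature line
    isNew <- grepl("^ {5}\\S", body)
    grp <- cumsum(isNew)
    keep <- grp > 0L
    units <- vapply(split(trimws(body[keep]), grp[keep]),
                    paste, character(1), collapse = "\n")
    for (u in units) {
      fl <- strsplit(u, "\n", fixed = TRUE)[[1L]]
      head <- strsplit(fl[1L], "\\s+")[[1L]]
      if (head[1L] != "CDS") next
      loc <- paste0(head[-1L], collapse = "")
      ## location may continue onto lines preceding the first qualifier
      rest <- fl[-1L]
      qual1 <- grep("^/", rest)
      nCont <- if (length(qual1)) min(qual1) - 1L else length(rest)
      if (nCont > 0L)
        loc <- paste0(loc, paste0(rest[seq_len(nCont)], collapse = ""))

      strand <- if (grepl("complement", loc)) "-" else "+"
      if (grepl("join\\(|order\\(", loc)) nJoin <- nJoin + 1L
      pos <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      if (!length(pos)) next
      quals <- fl[grepl("^/", fl)]
      getq <- function(name) {
        m <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub('^[^=]*=|"', "", m[1L])
      }
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = getq("locus_tag"),
        contig_id = contigId,
        start = min(pos), end = max(pos), strand = strand,
        cluster_id = NA_character_,
        product = getq("product"),
        protein_id = getq("protein_id"),
        stringsAsFactors = FALSE)
    }
    contigs[[r]] <- data.frame(contig_id = contigId, length = contigLen)
  }

  ft <- if (length(feats)) do.call(rbind, feats) else
    cbind(.emptyFeatureTable(), protein_id = character())
  miss <- is.na(ft$feature_id)
  ft$feature_id[miss] <- ft$protein_id[miss]
  miss <- is.na(ft$feature_id)
  if (any(miss))
    ft$feature_id[miss] <- sprintf("%s_CDS%04d", genomeId, which(miss))
  ft$protein_id <- NULL
  if (nJoin > 0L)
    .warnf("%d CDS with join()/order() locations collapsed to outermost span",
           nJoin)
  ct <- do.call(rbind, contigs)
  if (any(is.na(ct$length))) {
    for (i in which(is.na(ct$length))) {
      here <- ft$contig_id == ct$contig_id[i]
      ct$length[i] <- if (any(here)) max(ft$end[here]) else 1
    }
  }
  AnnotatedGenome(genomeId, features = ft, contigs = ct)
}
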