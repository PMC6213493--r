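#' Identify single-copy core genes (SCCGs)
#'
#' An SCCG is a homology cluster with exactly one member feature in every
#' genome of the set.
#'
#' @param gs a [GenomeSet-class] with cluster assignments attached.
#' @return an [SCCGSet-class] (possibly empty).
#' @export
identifySCCGs <- function(gs) {
  ft <- features(gs)
  n <- nGenomes(gs)
  cnt <- .clusterGenomeCounts(ft)
  ok <- if (length(cnt)) {
    rownames(cnt)[apply(cnt, 1L, function(v)
      length(v) == n && all(v == 1L))]
  } else character()
  # table() drops genomes with no clustered features from the columns;
  # require the full genome complement explicitly
  if (length(cnt) && ncol(cnt) < n) ok <- character()
  sub <- ft[!is.na(ft$cluster_id) & ft$cluster_id %in% ok, , drop = FALSE]
  sub <- sub[, c("genome_id", "cluster_id", "feature_id", "contig_id",
                 "start", "end", "strand"), drop = FALSE]
  sub$center <- (sub$start + sub$end) / 2
  sub <- sub[order(sub$genome_id, sub$cluster_id), , drop = FALSE]
  rownames(sub) <- NULL
  new("SCCGSet", clusterIds = sort(ok), features = sub,
      nGenomes = as.integer(n))
}

#' All pairwise center-to-center distances within a genome
#'
#' Returns every unordered pair of the given features that lies on the
#' same contig, with the absolute center-to-center distance in bp. Pairs
#' spanning different contigs are omitted (their distance is unknowable on
#' a fragmented assembly).
#'
#' @param genome a [AnnotatedGenome-class].
#' @param featureIds optional subset of feature ids (default: all).
#' @return `data.frame` with columns `feature_a`, `feature_b`,
#'   `distance_bp`.
#' @export
pairwiseCenterDistances <- function(genome, featureIds = NULL) {
  ft <- genome@features
  if (!is.null(featureIds)) {
    miss <- setdiff(featureIds, ft$feature_id)
    if (length(miss))
      .stopf("feature(s) not in genome '%s': %s", genome@genomeId,
             paste(utils::head(miss, 3L), collapse = ", "))
    ft <- ft[ft$feature_id %in% featureIds, , drop = FALSE]
  }
  out <- lapply(split(ft, ft$contig_id), function(sub) {
    n <- nrow(sub)
    if (n < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cen <- featureCenters(sub)
    data.frame(feature_a = sub$feature_id[idx[, 1L]],
               feature_b = sub$feature_id[idx[, 2L]],
               distance_bp = abs(cen[idx[, 1L]] - cen[idx[, 2L]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(feature_a = character(), feature_b = character(),
                      distance_bp = numeric())
  rownames(out) <- NULL
  out
}

#' Random-shuffle null model of pairwise gene distances
#'
#' The expected fraction of gene pairs falling within a growing distance
#' bin, if genes shuffled independently while preserving the genome's own
#' distance distribution: the empirical CDF of all pairwise
#' center-to-center distances between genes (all genes, not only SCCGs),
#' evaluated at each bin upper edge. Only same-contig pairs enter the
#' distribution (cross-contig distances are undefined).
#'
#' @param genome a [AnnotatedGenome-class] with at least 2 features.
#' @param binBp bin step in bp (default 1000).
#' @param maxBp largest bin upper edge in bp (default 280000).
#' @return `data.frame` with columns `bin_upper_bp`, `cdf`.
#' @export
randomShuffleNull <- function(genome, binBp = 1000, maxBp = 280000) {
  if (nrow(genome@features) < 2L)
    .stopf("genome '%s' has fewer than 2 features", genome@genomeId)
  d <- pairwiseCenterDistances(genome)$distance_bp
  edges <- seq(binBp, maxBp, by = binBp)
  cdf <- if (length(d)) vapply(edges, function(e) mean(d <= e), numeric(1))
  else rep(NA_real_, length(edges))
  data.frame(bin_upper_bp = edges, cdf = cdf)
}

#' Patristic distance between two genomes on a phylogeny
#'
#' Sum of branch lengths along the path between two tips.
#'
#' @param tree an [ape::phylo] with branch lengths (see [readNewick()]).
#' @param a,b tip labels (genome ids).
#' @return the patristic distance (0 when `a == b`).
#' @export
phyloDistance <- function(tree, a, b) {
  miss <- setdiff(c(a, b), tree$tip.label)
  if (length(miss))
    .stopf("genome(s) not tips of the phylogeny: %s",
           paste(miss, collapse = ", "))
  if (a == b) return(0)
  dm <- ape::cophenetic.phylo(tree)
  unname(dm[a, b])
}
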