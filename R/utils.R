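#' Feature centers
#'
#' Center of a feature is `(start + end) / 2`, possibly half-integral;
#' centers are kept exact (never rounded) before distance comparison, and
#' are invariant under strand flips of the same interval.
#'
#' @param x a feature `data.frame` with `start` and `end` columns.
#' @return numeric vector of centers in bp.
#' @export
featureCenters <- function(x) (x$start + x$end) / 2

## Index of features of `ft` (single-genome feature table) whose center is
## within `maxDist` (inclusive) of any of the given seed rows, same contig
## only. Returns integer row indices (seed rows included).
.windowMembers <- function(ft, seedRows, maxDist) {
  if (!length(seedRows)) return(integer())
  cen <- featureCenters(ft)
  hit <- logical(nrow(ft))
  for (i in seedRows) {
    hit <- hit | (ft$contig_id == ft$contig_id[i] &
                    abs(cen - cen[i]) <= maxDist)
  }
  which(hit)
}

## Per-genome occurrence count of each cluster id: named matrix-like
## data.frame cluster x genome counts, from the combined feature table.
.clusterGenomeCounts <- function(ft) {
  ft <- ft[!is.na(ft$cluster_id), , drop = FALSE]
  if (!nrow(ft))
    return(table(factor(character()), factor(character())))
  table(ft$cluster_id, ft$genome_id)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
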