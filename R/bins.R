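#' @rdname binTable
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' Bin table of a distance-conservation curve
#'
#' @param x a [ConstrainedBinCurve-class] or [GrowingBinCurve-class].
#' @return the per-bin `data.frame` (see the class documentation).
#' @name binTable
NULL

#' @rdname binTable
#' @export
setMethod("binTable", "ConstrainedBinCurve", function(x) x@table)

#' @rdname binTable
#' @export
setMethod("binTable", "GrowingBinCurve", function(x) x@table)

## Distance matrix (genomes x SCCG cluster pairs) of center-to-center
## distances; NA where the pair is not measurable (different contigs).
## Returns list(D = matrix, pairs = data.frame(cluster_a, cluster_b)).
.sccgPairDistances <- function(gs, sccg) {
  K <- sccg@clusterIds
  nK <- length(K)
  if (nK < 2L) .stopf("need at least 2 SCCGs")
  gids <- genomeIds(gs)
  idx <- which(upper.tri(matrix(0, nK, nK)), arr.ind = TRUE)
  P <- nrow(idx)
  D <- matrix(NA_real_, length(gids), P, dimnames = list(gids, NULL))
  sf <- sccg@features
  for (g in gids) {
    sub <- sf[sf$genome_id == g, , drop = FALSE]
    pos <- match(K, sub$cluster_id)
    cen <- sub$center[pos]
    ctg <- sub$contig_id[pos]
    a <- idx[, 1L]; b <- idx[, 2L]
    same <- !is.na(ctg[a]) & !is.na(ctg[b]) & ctg[a] == ctg[b]
    d <- abs(cen[a] - cen[b])
    d[!same] <- NA_real_
    D[g, ] <- d
  }
  list(D = D, pairs = data.frame(cluster_a = K[idx[, 1L]],
                                 cluster_b = K[idx[, 2L]],
                                 stringsAsFactors = FALSE))
}

#' Strictly constrained bin analysis of SCCG pair distances
#'
#' For each seed genome, every SCCG pair is assigned to the 1-kbp bin of
#' its center-to-center distance. The analogous pair in another genome
#' counts as conserved when its distance falls within the seed pair's bin
#' widened by `bufferBp` on each side. Each genome serves as seed in turn
#' and seed pairs are pooled; per bin, the curve reports the fraction of
#' seed pairs conserved in at least 100/90/80/70% of the other genomes.
#' Pairs that are absent or split across contigs in a comparison genome
#' count as not conserved; bins containing no seed pairs are `NA`.
#'
#' @param gs a [GenomeSet-class] of at least 2 genomes.
#' @param sccg the [SCCGSet-class] of `gs` (see [identifySCCGs()]).
#' @param binBp bin width in bp (default 1000).
#' @param bufferBp buffer added on each side of the seed pair's bin
#'   (default 250).
#' @param maxBp largest distance considered (default 280000).
#' @param thresholds genome-fraction thresholds (default 1, 0.9, 0.8, 0.7).
#' @return a [ConstrainedBinCurve-class].
#' @export
constrainedBinAnalysis <- function(gs, sccg, binBp = 1000, bufferBp = 250,
                                   maxBp = 280000,
                                   thresholds = c(1, 0.9, 0.8, 0.7)) {
  if (nGenomes(gs) < 2L) .stopf("need at least 2 genomes")
  pd <- .sccgPairDistances(gs, sccg)
  D <- pd$D
  n <- nrow(D)
  nBins <- ceiling(maxBp / binBp)
  denom <- numeric(nBins)
  numer <- matrix(0, length(thresholds), nBins)

  for (s in seq_len(n)) {
    d0 <- D[s, ]
    use <- which(!is.na(d0) & d0 < nBins * binBp)
    if (!length(use)) next
    bin <- floor(d0[use] / binBp)           # 0-based bin index
    lo <- bin * binBp - bufferBp
    hi <- (bin + 1) * binBp + bufferBp
    Do <- D[-s, use, drop = FALSE]
    ok <- sweep(Do, 2L, lo, ">=") & sweep(Do, 2L, hi, "<=")
    ok[is.na(Do)] <- FALSE
    fracGen <- colSums(ok) / (n - 1L)
    b1 <- bin + 1L                          # 1-based
    for (ti in seq_along(thresholds)) {
      pass <- fracGen >= thresholds[ti] - 1e-12
      numer[ti, ] <- numer[ti, ] + tabulate(b1[pass], nbins = nBins)
    }
    denom <- denom + tabulate(b1, nbins = nBins)
  }

  tab <- data.frame(bin_lower_bp = (seq_len(nBins) - 1L) * binBp,
                    bin_upper_bp = seq_len(nBins) * binBp,
                    n_seed_pairs = denom)
  for (ti in seq_along(thresholds)) {
    v <- ifelse(denom > 0, numer[ti, ] / denom, NA_real_)
    tab[[sprintf("frac_%g", 100 * thresholds[ti])]] <- v
  }
  new("ConstrainedBinCurve", table = tab,
      params = list(bin_bp = binBp, buffer_bp = bufferBp, max_bp = maxBp,
                    thresholds = thresholds))
}

#' Growing bin analysis of one ordered genome pair
#'
#' For each bin `[0, b]` (b growing by `binBp` up to `maxBp`), the
#' observed fraction is the number of SCCG pairs with center-to-center
#' distance `<= b` in both genomes divided by the number with distance
#' `<= b` in the first genome. The random-shuffle null CDFs of both
#' genomes ([randomShuffleNull()]) are attached, the second genome's null
#' is subtracted from the observed curve, and the half-maximal
#' detectability threshold is computed ([halfMaxThreshold()]).
#'
#' @param ga,gb [AnnotatedGenome-class] objects: the ordered pair (denominator from
#'   `ga`).
#' @param sccg an [SCCGSet-class] covering both genomes.
#' @param binBp,maxBp bin step and cap in bp (defaults 1000, 280000).
#' @param tree optional [ape::phylo]; when given, the pair's patristic
#'   distance is attached.
#' @return a [GrowingBinCurve-class].
#' @export
growingBinAnalysis <- function(ga, gb, sccg, binBp = 1000, maxBp = 280000,
                               tree = NULL) {
  self <- identical(ga@genomeId, gb@genomeId)
  gsAB <- GenomeSet(if (self) list(ga) else list(ga, gb))
  sf <- sccg@features
  if (!all(c(ga@genomeId, gb@genomeId) %in% sf$genome_id))
    .stopf("both genomes must be covered by the SCCGSet")
  pd <- .sccgPairDistances(gsAB, sccg)
  dA <- pd$D[ga@genomeId, ]
  dB <- if (self) dA else pd$D[gb@genomeId, ]

  edges <- seq(binBp, maxBp, by = binBp)
  inA <- outer(dA, edges, "<=")        # pairs x bins
  inA[is.na(dA), ] <- FALSE
  both <- inA & outer(ifelse(is.na(dB), Inf, dB), edges, "<=")
  nA <- colSums(inA)
  observed <- ifelse(nA > 0, colSums(both) / nA, NA_real_)

  nullA <- randomShuffleNull(ga, binBp, maxBp)$cdf
  nullB <- randomShuffleNull(gb, binBp, maxBp)$cdf
  tab <- data.frame(bin_upper_bp = edges, n_pairs_a = nA,
                    observed = observed, null_a = nullA, null_b = nullB,
                    subtracted = observed - nullB)
  curve <- new("GrowingBinCurve", genomeA = ga@genomeId,
               genomeB = gb@genomeId, table = tab,
               halfMax = list(), params = list(bin_bp = binBp,
                                               max_bp = maxBp))
  curve@halfMax <- halfMaxThreshold(curve)
  if (!is.null(tree))
    curve@phyloDistance <- phyloDistance(tree, ga@genomeId, gb@genomeId)
  curve
}

#' Half-maximal detectability threshold of a growing-bin curve
#'
#' The initial conservation is the subtracted curve's value at the first
#' occupied bin. The threshold is the smallest bin upper edge at which the
#' subtracted curve first drops to half the initial value or below: the
#' largest bin size at which distance conservation is still reliably
#' non-random. When the curve never reaches half-max the cap is returned
#' with `flagged = TRUE`.
#'
#' @param curve a [GrowingBinCurve-class].
#' @return list with `threshold_bp`, `initial`, `flagged`.
#' @export
halfMaxThreshold <- function(curve) {
  tab <- curve@table
  occ <- which(!is.na(tab$subtracted))
  if (!length(occ))
    return(list(threshold_bp = curve@params$max_bp, initial = NA_real_,
                flagged = TRUE))
  initial <- tab$subtracted[occ[1L]]
  hit <- occ[tab$subtracted[occ] <= initial / 2 + 1e-12]
  if (length(hit))
    list(threshold_bp = tab$bin_upper_bp[hit[1L]], initial = initial,
         flagged = FALSE)
  else
    list(threshold_bp = curve@params$max_bp, initial = initial,
         flagged = TRUE)
}
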