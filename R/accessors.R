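#' Construct an AnnotatedGenome
#'
#' @param genomeId single genome identifier.
#' @param contigs `data.frame` with columns `contig_id`, `length` (bp); if
#'   omitted, one contig per distinct `contig_id` in `features`, long
#'   enough to hold its features.
#' @param features `data.frame` of features; missing optional columns
#'   (`cluster_id`, `product`) are filled with `NA`. Rows are sorted by
#'   `(contig_id, start)` on construction.
#'
#' @return a [AnnotatedGenome-class] object.
#' @export
AnnotatedGenome <- function(genomeId, features = .emptyFeatureTable(), contigs = NULL) {
  features <- .normalizeFeatureTable(as.data.frame(features))
  if (is.null(contigs)) {
    if (nrow(features)) {
      len <- vapply(split(features$end, features$contig_id), max, numeric(1))
      contigs <- data.frame(contig_id = names(len), length = unname(len),
                            stringsAsFactors = FALSE)
    } else {
      contigs <- data.frame(contig_id = character(), length = numeric(),
                            stringsAsFactors = FALSE)
    }
  }
  contigs <- as.data.frame(contigs)
  contigs$contig_id <- as.character(contigs$contig_id)
  contigs$length <- as.numeric(contigs$length)
  rownames(contigs) <- NULL
  new("AnnotatedGenome", genomeId = as.character(genomeId),
      contigs = contigs[, c("contig_id", "length"), drop = FALSE],
      features = features)
}

#' Construct an AnnotatedGenomeSet
#'
#' @param genomes list of [AnnotatedGenome-class] objects.
#' @return a [GenomeSet-class].
#' @export
GenomeSet <- function(genomes = list()) {
  ids <- vapply(genomes, function(g) g@genomeId, character(1))
  names(genomes) <- ids
  new("GenomeSet", genomes = genomes)
}

#' Gang detection parameters
#'
#' @param maxGenomicDistance collinearity window in bp (inclusive).
#' @param minGenomePrevalence minimum genomes a seed/member cluster must
#'   occur in.
#' @param paralogCorrectionThreshold minimum genomes for edge-paralog
#'   admission.
#' @param largeClusterThreshold member count above which (strictly) a
#'   cluster is "large".
#' @param minGangClusters minimum distinct gang cluster ids.
#' @return a [GangParams-class].
#' @export
GangParams <- function(maxGenomicDistance = 3500,
                       minGenomePrevalence = 34,
                       paralogCorrectionThreshold = 15,
                       largeClusterThreshold = 80,
                       minGangClusters = 3) {
  new("GangParams",
      maxGenomicDistance = maxGenomicDistance,
      minGenomePrevalence = minGenomePrevalence,
      paralogCorrectionThreshold = paralogCorrectionThreshold,
      largeClusterThreshold = largeClusterThreshold,
      minGangClusters = minGangClusters)
}

#' Accessors for Genome objects
#'
#' @param x a [AnnotatedGenome-class] (or, for `features`, also a
#'   [GenomeSet-class], [ClusterGang-class] or [GeneGang-class]).
#' @param ... unused.
#' @name Genome-accessors
#' @aliases genomeId contigs features
NULL

#' @rdname Genome-accessors
#' @export
setMethod("genomeId", "AnnotatedGenome", function(x) x@genomeId)

#' @rdname Genome-accessors
#' @export
setMethod("contigs", "AnnotatedGenome", function(x) x@contigs)

#' @rdname Genome-accessors
#' @export
setMethod("features", "AnnotatedGenome", function(x, ...) x@features)

#' Accessors for GenomeSet objects
#'
#' `features()` on a GenomeSet returns the combined feature table with a
#' leading `genome_id` column; `clusterMap()` returns that table split by
#' `cluster_id` (unclustered features excluded), so that for every cluster
#' the map lists exactly the features carrying that id.
#'
#' @param x a [GenomeSet-class].
#' @param ... unused.
#' @name GenomeSet-accessors
#' @aliases genomes nGenomes genomeIds clusterMap
NULL

#' @rdname GenomeSet-accessors
#' @export
setMethod("genomes", "GenomeSet", function(x) x@genomes)

#' @rdname GenomeSet-accessors
#' @export
setMethod("nGenomes", "GenomeSet", function(x) length(x@genomes))

#' @rdname GenomeSet-accessors
#' @export
setMethod("genomeIds", "GenomeSet", function(x) names(x@genomes))

#' @rdname GenomeSet-accessors
#' @export
setMethod("features", "GenomeSet", function(x, ...) {
  if (!length(x@genomes)) {
    out <- cbind(genome_id = character(), .emptyFeatureTable())
    return(out)
  }
  parts <- lapply(x@genomes, function(g) {
    ft <- g@features
    if (nrow(ft)) cbind(genome_id = g@genomeId, ft, stringsAsFactors = FALSE)
    else cbind(genome_id = character(), .emptyFeatureTable())
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
})

#' @rdname GenomeSet-accessors
#' @export
setMethod("clusterMap", "GenomeSet", function(x) {
  ft <- features(x)
  ft <- ft[!is.na(ft$cluster_id), , drop = FALSE]
  split(ft, ft$cluster_id)
})

#' Accessors for SCCGSet, ClusterGang and GeneGang objects
#'
#' @param x the object.
#' @param ... unused.
#' @name gang-accessors
#' @aliases clusterIds gangId ruliness gangFlags
NULL

#' @rdname gang-accessors
#' @export
setMethod("clusterIds", "SCCGSet", function(x) x@clusterIds)

#' @rdname gang-accessors
#' @export
setMethod("features", "SCCGSet", function(x, ...) x@features)

#' @rdname gang-accessors
#' @export
setMethod("features", "ClusterGang", function(x, ...) x@features)

#' @rdname gang-accessors
#' @export
setMethod("clusterIds", "ClusterGang", function(x) {
  sort(unique(x@features$cluster_id[!is.na(x@features$cluster_id)]))
})

#' @rdname gang-accessors
#' @export
setMethod("features", "GeneGang", function(x, ...) x@features)

#' @rdname gang-accessors
#' @export
setMethod("clusterIds", "GeneGang", function(x) x@clusterIds)

#' @rdname gang-accessors
#' @export
setMethod("gangId", "GeneGang", function(x) x@gangId)

#' @rdname gang-accessors
#' @export
setMethod("ruliness", "GeneGang", function(x) x@ruliness)

#' @rdname gang-accessors
#' @export
setMethod("gangFlags", "GeneGang", function(x) x@flags)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome", object@genomeId, "|",
      nrow(object@contigs), "contig(s),",
      nrow(object@features), "features,",
      sum(object@contigs$length), "bp\n")
})

setMethod("show", "GenomeSet", function(object) {
  ft <- features(object)
  ncl <- length(unique(ft$cluster_id[!is.na(ft$cluster_id)]))
  cat("GenomeSet of", length(object@genomes), "genomes |",
      nrow(ft), "features,", ncl, "homology clusters\n")
})

setMethod("show", "SCCGSet", function(object) {
  cat("SCCGSet:", length(object@clusterIds),
      "single-copy core clusters over", object@nGenomes, "genomes\n")
})

setMethod("show", "GangParams", function(object) {
  cat("GangParams: window", object@maxGenomicDistance, "bp; prevalence >=",
      object@minGenomePrevalence, "genomes; paralog threshold",
      object@paralogCorrectionThreshold, "; large cluster >",
      object@largeClusterThreshold, "; min clusters",
      object@minGangClusters, "\n")
})

setMethod("show", "ClusterGang", function(object) {
  cat("ClusterGang seeded by", object@seedCluster, "|",
      length(unique(object@features$genome_id)), "genomes,",
      nrow(object@features), "member features\n")
})

setMethod("show", "GeneGang", function(object) {
  cat("GeneGang", object@gangId, "|", length(object@clusterIds),
      "cluster ids, ruliness",
      if (length(object@ruliness)) sprintf("%.3f", min(object@ruliness))
      else "NA",
      "|", nrow(object@features), "features in",
      length(unique(object@features$genome_id)), "genomes\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ConstrainedBinCurve", function(object) {
  occ <- sum(!is.na(object@table[[4L]]))
  cat("ConstrainedBinCurve:", nrow(object@table), "bins (",
      occ, "occupied ), buffer", object@params$buffer_bp, "bp\n")
})

setMethod("show", "GrowingBinCurve", function(object) {
  cat("GrowingBinCurve", object@genomeA, "vs", object@genomeB,
      "| half-max threshold", object@halfMax$threshold_bp, "bp",
      if (isTRUE(object@halfMax$flagged)) "(never reached)" else "", "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenomes, "genomes,",
      paste(object@nGenesRange, collapse = "-"), "genes,",
      object@nCoreClusters, "core clusters,",
      length(object@plantedGangSizes), "planted gangs, shuffle",
      object@shuffleIntensity, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@gangClusters), "planted gangs,",
      nrow(object@events), "logged events\n")
})
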