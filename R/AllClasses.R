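#' @import methods
NULL

## Canonical feature table columns. All coordinates are 1-based inclusive
## base pairs; gene "centers" (start+end)/2 may be half-integral and are
## never rounded before distance comparison.
.FEATURE_COLS <- c("feature_id", "contig_id", "start", "end",
                   "strand", "cluster_id", "product")

.emptyFeatureTable <- function() {
  data.frame(feature_id = character(), contig_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             cluster_id = character(), product = character(),
             stringsAsFactors = FALSE)
}

.normalizeFeatureTable <- function(df) {
  if (nrow(df) == 0L) return(.emptyFeatureTable())
  for (col in .FEATURE_COLS)
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
  df <- df[, .FEATURE_COLS, drop = FALSE]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$feature_id <- as.character(df$feature_id)
  df$contig_id <- as.character(df$contig_id)
  df$strand <- as.character(df$strand)
  df$cluster_id <- as.character(df$cluster_id)
  df$product <- as.character(df$product)
  df <- df[order(df$contig_id, df$start, df$end, df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' AnnotatedGenome: one annotated genome
#'
#' Container for a single annotated genome: an ordered set of contigs with
#' lengths and a table of protein-coding features sorted by
#' `(contig_id, start)`. Coordinates are 1-based inclusive. Genomes are
#' treated as linear: center-to-center distances never wrap, and distances
#' across contig breaks are undefined (treated as infinite by all analyses).
#'
#' @slot genomeId single genome identifier.
#' @slot contigs `data.frame` with columns `contig_id`, `length`.
#' @slot features `data.frame` with columns `feature_id`, `contig_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `cluster_id` (may be `NA` for
#'   unclustered genes), `product`.
#'
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
         representation(genomeId = "character",
                        contigs = "data.frame",
                        features = "data.frame"))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  ct <- object@contigs
  if (!all(c("contig_id", "length") %in% names(ct)))
    msg <- c(msg, "contigs needs columns contig_id, length")
  else if (anyDuplicated(ct$contig_id))
    msg <- c(msg, "duplicated contig_id")
  ft <- object@features
  if (!all(.FEATURE_COLS %in% names(ft))) {
    msg <- c(msg, "features table missing canonical columns")
    return(if (length(msg)) msg else TRUE)
  }
  if (nrow(ft)) {
    if (anyDuplicated(ft$feature_id))
      msg <- c(msg, "feature_id not unique within genome")
    if (any(ft$start < 1) || any(ft$end < ft$start))
      msg <- c(msg, "features must satisfy 1 <= start <= end")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (!all(ft$contig_id %in% ct$contig_id))
      msg <- c(msg, "feature on contig absent from contig table")
    else {
      len <- ct$length[match(ft$contig_id, ct$contig_id)]
      if (any(ft$end > len))
        msg <- c(msg, "feature extends beyond contig length")
    }
    o <- order(ft$contig_id, ft$start, ft$end, ft$feature_id)
    if (!identical(o, seq_len(nrow(ft))))
      msg <- c(msg, "features must be sorted by (contig_id, start)")
  }
  if (length(msg)) msg else TRUE
})

#' GenomeSet: the collection all analyses run on
#'
#' A set of [AnnotatedGenome-class] objects plus the homology-cluster assignments
#' carried on their feature tables. The cluster map (cluster_id to member
#' features across all genomes) is derived from the feature tables by
#' [clusterMap()] so the two can never disagree.
#'
#' @slot genomes named list of [AnnotatedGenome-class] objects (names = genome ids).
#'
#' @exportClass GenomeSet
setClass("GenomeSet", representation(genomes = "list"))

setValidity("GenomeSet", function(object) {
  msg <- character()
  gl <- object@genomes
  if (length(gl)) {
    if (!all(vapply(gl, is, logical(1), "AnnotatedGenome")))
      msg <- c(msg, "genomes must all be Genome objects")
    else {
      ids <- vapply(gl, function(g) g@genomeId, character(1))
      if (anyDuplicated(ids)) msg <- c(msg, "duplicated genome ids")
      if (!identical(names(gl), unname(ids)))
        msg <- c(msg, "genome list names must equal genome ids")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SCCGSet: single-copy core genes
#'
#' The set of homology clusters present exactly once in every genome of a
#' [GenomeSet-class], with their member features.
#'
#' @slot clusterIds character vector of SCCG cluster ids.
#' @slot features `data.frame` with one row per (genome, cluster): columns
#'   `genome_id`, `cluster_id`, `feature_id`, `contig_id`, `start`, `end`,
#'   `strand`, `center`.
#' @slot nGenomes number of genomes in the set the SCCGs were called on.
#'
#' @exportClass SCCGSet
setClass("SCCGSet",
         representation(clusterIds = "character",
                        features = "data.frame",
                        nGenomes = "integer"))

#' GangParams: tuning parameters of gene-gang detection
#'
#' @slot maxGenomicDistance collinearity window, bp: two features are
#'   co-localized when their center-to-center distance is `<=` this value
#'   (inclusive). Default 3500.
#' @slot minGenomePrevalence minimum number of genomes in which a seed
#'   cluster (and, within a cluster gang, any member cluster) must occur.
#'   Default 34 (of 41).
#' @slot paralogCorrectionThreshold minimum number of genomes in which an
#'   edge paralog must be found next to gang members before it is admitted.
#'   Default 15; 14 is the alternative published value.
#' @slot largeClusterThreshold clusters with strictly more than this many
#'   members across the whole set are "large" (highly paralogous) and never
#'   seed gangs. Default 80.
#' @slot minGangClusters minimum number of distinct gang cluster ids for a
#'   gang to be retained. Default 3.
#'
#' @exportClass GangParams
setClass("GangParams",
         representation(maxGenomicDistance = "numeric",
                        minGenomePrevalence = "numeric",
                        paralogCorrectionThreshold = "numeric",
                        largeClusterThreshold = "numeric",
                        minGangClusters = "numeric"),
         prototype(maxGenomicDistance = 3500,
                   minGenomePrevalence = 34,
                   paralogCorrectionThreshold = 15,
                   largeClusterThreshold = 80,
                   minGangClusters = 3))

setValidity("GangParams", function(object) {
  v <- c(object@maxGenomicDistance, object@minGenomePrevalence,
         object@paralogCorrectionThreshold, object@largeClusterThreshold,
         object@minGangClusters)
  if (any(!is.finite(v)) || any(v <= 0))
    "all parameters must be positive finite numbers"
  else TRUE
})

## Gang feature tables carry genome_id plus the canonical feature columns
## plus an is_seed flag.
.GANG_COLS <- c("genome_id", .FEATURE_COLS, "is_seed")

#' ClusterGang: one seed cluster's genomic groupings
#'
#' The collection of genomic groupings (seed features plus features within
#' the collinearity window) of a single seed cluster, one grouping per
#' genome where the seed occurs.
#'
#' @slot seedCluster the seed cluster id.
#' @slot features `data.frame` of member features across genomes (columns
#'   `genome_id`, canonical feature columns, `is_seed`).
#'
#' @exportClass ClusterGang
setClass("ClusterGang",
         representation(seedCluster = "character", features = "data.frame"))

#' GeneGang: a merged, disjoint gang of co-localized genes
#'
#' @slot gangId stable identifier assigned by [detectGeneGangs()].
#' @slot clusterIds the gang cluster ids (clusters of all member features,
#'   unclustered members excluded), sorted.
#' @slot features member features across genomes (columns `genome_id`,
#'   canonical feature columns, `is_seed`).
#' @slot ruliness named numeric: per gang cluster id, the fraction of
#'   genomes containing at least one member feature of that cluster.
#' @slot nGenomes number of genomes of the parent set.
#' @slot flags character vector of warnings attached during construction
#'   (e.g. `"degenerate"` after a ruliness filter left fewer clusters than
#'   the minimum).
#'
#' @exportClass GeneGang
setClass("GeneGang",
         representation(gangId = "character",
                        clusterIds = "character",
                        features = "data.frame",
                        ruliness = "numeric",
                        nGenomes = "integer",
                        flags = "character"),
         prototype(flags = character()))

#' ConstrainedBinCurve: strictly constrained bin analysis result
#'
#' Per 1-kbp distance bin, the fraction of seed SCCG pairs whose
#' center-to-center distance is conserved (within the seed pair's bin
#' widened by a buffer) in at least 100/90/80/70% of the other genomes.
#' Bins containing no seed pairs are reported as `NA`, not 0.
#'
#' @slot table `data.frame`: `bin_lower_bp`, `bin_upper_bp`, `n_seed_pairs`,
#'   and one `frac_<pct>` column per genome-fraction threshold.
#' @slot params list echoing `bin_bp`, `buffer_bp`, `max_bp`, `thresholds`.
#'
#' @exportClass ConstrainedBinCurve
setClass("ConstrainedBinCurve",
         representation(table = "data.frame", params = "list"))

#' GrowingBinCurve: growing bin analysis of one ordered genome pair
#'
#' @slot genomeA,genomeB the ordered genome pair (denominator pairs are
#'   those within the bin in `genomeA`).
#' @slot table `data.frame`: `bin_upper_bp`, `n_pairs_a` (pairs within the
#'   bin in genome A), `observed` (fraction also within the bin in genome
#'   B; `NA` where no eligible pairs), `null_a`, `null_b` (random-shuffle
#'   CDFs of each genome), `subtracted` (`observed - null_b`).
#' @slot halfMax list: `threshold_bp` (smallest bin at which the subtracted
#'   curve first drops to half its initial value), `initial`, `flagged`
#'   (TRUE when the curve never reaches half-max and the cap is returned).
#' @slot phyloDistance patristic distance of the pair (NA if no tree given).
#' @slot params list echoing `bin_bp`, `max_bp`.
#'
#' @exportClass GrowingBinCurve
setClass("GrowingBinCurve",
         representation(genomeA = "character", genomeB = "character",
                        table = "data.frame", halfMax = "list",
                        phyloDistance = "numeric", params = "list"),
         prototype(phyloDistance = NA_real_))

#' SimConfig: synthetic genome-set configuration
#'
#' Defaults emulate the corpus scale the package targets: about 41 genomes
#' of roughly 330 kbp carrying 319-416 genes each, a core-gene complement
#' present in every genome, a few large paralog families, planted gangs of
#' 3-10 members, and between-genome shuffling by block inversion and
#' translocation.
#'
#' @slot nGenomes number of genomes (default 41).
#' @slot nGenesRange inclusive range the per-genome (ancestor) gene count
#'   is drawn from (default 319-416).
#' @slot nCoreClusters clusters present in every genome, single copy
#'   (default 155); planted gang clusters are drawn from this budget.
#' @slot plantedGangSizes integer sizes of planted gangs (default
#'   3, 4, 5, 7, 10); members of one gang occupy consecutive gene slots so
#'   consecutive centers sit well inside the collinearity window.
#' @slot gangSpacingBp minimum center-to-center separation between a gang
#'   member and any other conserved (core or gang) gene (default 7000,
#'   i.e. twice the default collinearity window).
#' @slot largeFamilies named integer: total member count per large paralog
#'   family (default two families of 90 members spread over the genomes).
#' @slot shuffleIntensity expected number of block inversion/translocation
#'   events applied per genome (default 20).
#' @slot gangDisruptionRate probability that a planted gang loses one
#'   member in a given genome (default 0).
#' @slot accessoryPrevalenceRange each accessory (non-core) cluster is
#'   present in a uniformly drawn fraction of genomes within this range
#'   (default 0.45-0.8): accessory genes are by definition below the
#'   core/conservation bar, so their prevalence is bounded away from it.
#' @slot geneLengthRange uniform range of gene lengths, bp (default
#'   300-1500).
#' @slot gapRange uniform range of intergenic gaps, bp (default 50-90).
#'
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nGenomes = "integer",
                        nGenesRange = "integer",
                        nCoreClusters = "integer",
                        plantedGangSizes = "integer",
                        gangSpacingBp = "numeric",
                        largeFamilies = "integer",
                        shuffleIntensity = "numeric",
                        gangDisruptionRate = "numeric",
                        accessoryPrevalenceRange = "numeric",
                        geneLengthRange = "numeric",
                        gapRange = "numeric"),
         prototype(nGenomes = 41L,
                   nGenesRange = c(319L, 416L),
                   nCoreClusters = 155L,
                   plantedGangSizes = c(3L, 4L, 5L, 7L, 10L),
                   gangSpacingBp = 7000,
                   largeFamilies = c(LF001 = 90L, LF002 = 90L),
                   shuffleIntensity = 20,
                   gangDisruptionRate = 0,
                   accessoryPrevalenceRange = c(0.45, 0.8),
                   geneLengthRange = c(300, 1500),
                   gapRange = c(50, 90)))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenomes < 2L) msg <- c(msg, "need at least 2 genomes")
  if (length(object@nGenesRange) != 2L ||
      object@nGenesRange[1] > object@nGenesRange[2])
    msg <- c(msg, "nGenesRange must be an increasing pair")
  if (length(object@plantedGangSizes) &&
      (any(object@plantedGangSizes < 3L) || any(object@plantedGangSizes > 10L)))
    msg <- c(msg, "planted gang sizes must lie in 3..10")
  if (sum(object@plantedGangSizes) > object@nCoreClusters)
    msg <- c(msg, "planted gangs exceed the core-cluster budget")
  if (object@gangDisruptionRate < 0 || object@gangDisruptionRate > 1)
    msg <- c(msg, "gangDisruptionRate must be in [0,1]")
  apr <- object@accessoryPrevalenceRange
  if (length(apr) != 2L || apr[1] <= 0 || apr[2] > 1 || apr[1] > apr[2])
    msg <- c(msg, "accessoryPrevalenceRange must be an increasing pair in (0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted-structure manifest of a simulated genome set
#'
#' @slot gangClusters list (one element per planted gang) of cluster-id
#'   vectors.
#' @slot gangFeatures `data.frame`: `gang`, `genome_id`, `feature_id`,
#'   `cluster_id` for every planted gang member feature actually emitted.
#' @slot events `data.frame` log of per-genome rearrangement and deletion
#'   events: `genome_id`, `type`, `block_start`, `block_end`, `detail`.
#' @slot config the [SimConfig-class] used.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(gangClusters = "list",
                        gangFeatures = "data.frame",
                        events = "data.frame",
                        config = "SimConfig"))
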