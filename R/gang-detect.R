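#' Classify homology clusters into seed and large clusters
#'
#' A cluster found strictly more than `largeClusterThreshold` times across
#' the whole set is "large" (highly paralogous; it never seeds a gang).
#' All other clusters are seed clusters.
#'
#' @param gs a [GenomeSet-class] with clusters attached.
#' @param params a [GangParams-class].
#' @return list with character vectors `seed` and `large`.
#' @export
classifyClusters <- function(gs, params = GangParams()) {
  ft <- features(gs)
  ft <- ft[!is.na(ft$cluster_id), , drop = FALSE]
  sizes <- table(ft$cluster_id)
  large <- names(sizes)[sizes > params@largeClusterThreshold]
  list(seed = sort(setdiff(names(sizes), large)), large = sort(large))
}

#' Build the genomic grouping of a seed cluster in one genome
#'
#' All features of the seed cluster present in the genome become seed
#' features; the grouping is the union, over seed features, of all
#' features within `maxGenomicDistance` center-to-center (inclusive, either
#' strand, either side, same contig). When a split or duplicated gene
#' yields several seed features, each contributes its own window and the
#' results are combined.
#'
#' @param genome a [AnnotatedGenome-class].
#' @param seedCluster a cluster id.
#' @param params a [GangParams-class].
#' @return `data.frame` of member features (canonical columns plus
#'   `is_seed`), or `NULL` when the seed cluster is absent from the
#'   genome.
#' @export
buildGrouping <- function(genome, seedCluster, params = GangParams()) {
  ft <- genome@features
  seedRows <- which(!is.na(ft$cluster_id) & ft$cluster_id == seedCluster)
  if (!length(seedRows)) return(NULL)
  rows <- .windowMembers(ft, seedRows, params@maxGenomicDistance)
  out <- ft[rows, , drop = FALSE]
  out$is_seed <- rows %in% seedRows
  rownames(out) <- NULL
  out
}

#' Form cluster gangs from seed clusters
#'
#' One [ClusterGang-class] per seed cluster, holding its genomic grouping
#' from every genome in which the seed occurs. Seeds absent everywhere are
#' dropped.
#'
#' @param gs a [GenomeSet-class].
#' @param seeds character vector of seed cluster ids (see
#'   [classifyClusters()]).
#' @param params a [GangParams-class].
#' @return list of [ClusterGang-class] objects, named by seed cluster.
#' @export
buildClusterGangs <- function(gs, seeds, params = GangParams()) {
  gangs <- lapply(seeds, function(sc) {
    parts <- lapply(gs@genomes, function(g) {
      grp <- buildGrouping(g, sc, params)
      if (is.null(grp)) return(NULL)
      cbind(genome_id = g@genomeId, grp, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, parts)
    if (is.null(tab) || !nrow(tab)) return(NULL)
    rownames(tab) <- NULL
    new("ClusterGang", seedCluster = sc, features = tab)
  })
  names(gangs) <- seeds
  gangs[!vapply(gangs, is.null, logical(1))]
}

#' Prevalence filter on cluster gangs
#'
#' Retains only the cluster gangs whose seed cluster occurs in at least
#' `minGenomePrevalence` genomes, and within each retained gang keeps only
#' the conserved members of the collinear window: features whose cluster
#' occurs in the gang's groupings in at least `minGenomePrevalence`
#' genomes (seed features always qualify). Unclustered features cannot
#' meet the bar and are dropped here; consistently co-localized clusters
#' are exactly what survives, which is what makes the later merge step
#' converge to biologically meaningful components instead of one
#' all-encompassing gang.
#'
#' @param gangs list of [ClusterGang-class] objects.
#' @param params a [GangParams-class].
#' @return filtered list of [ClusterGang-class] objects.
#' @export
prevalenceFilter <- function(gangs, params = GangParams()) {
  out <- lapply(gangs, function(cg) {
    tab <- cg@features
    seedPrev <- length(unique(tab$genome_id[tab$is_seed]))
    if (seedPrev < params@minGenomePrevalence) return(NULL)
    tab2 <- tab[!is.na(tab$cluster_id), , drop = FALSE]
    prev <- vapply(split(tab2$genome_id, tab2$cluster_id),
                   function(g) length(unique(g)), numeric(1))
    keepCl <- names(prev)[prev >= params@minGenomePrevalence]
    tab <- tab[!is.na(tab$cluster_id) & tab$cluster_id %in% keepCl, ,
               drop = FALSE]
    if (!nrow(tab)) return(NULL)
    rownames(tab) <- NULL
    new("ClusterGang", seedCluster = cg@seedCluster, features = tab)
  })
  out[!vapply(out, is.null, logical(1))]
}

## Union-find over 1..n
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge cluster gangs into disjoint gene gangs
#'
#' Two cluster gangs overlap when they share any cluster id among the
#' clusters of all their member features; overlapping gangs are merged,
#' repeatedly, until no genomic feature belongs to more than one gang.
#' The fixpoint of that iteration is the set of connected components of
#' the cluster-id overlap graph, which is what is computed (in one pass,
#' by union-find). Groupings of merged gangs are unioned per genome with
#' features deduplicated; the result is independent of input order.
#'
#' @param gangs list of [ClusterGang-class] objects.
#' @return list of [GeneGang-class] objects (ruliness not yet computed;
#'   see [detectGeneGangs()] for the full pipeline).
#' @export
mergeToGeneGangs <- function(gangs) {
  if (!length(gangs)) return(list())
  clSets <- lapply(gangs, function(cg)
    unique(cg@features$cluster_id[!is.na(cg@features$cluster_id)]))
  n <- length(gangs)
  parent <- seq_len(n)
  owner <- new.env(parent = emptyenv())   # cluster_id -> first gang index
  for (i in seq_len(n)) {
    for (cl in clSets[[i]]) {
      j <- owner[[cl]]
      if (is.null(j)) assign(cl, i, envir = owner)
      else {
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  comps <- split(seq_len(n), roots)

  out <- lapply(comps, function(idx) {
    tab <- do.call(rbind, lapply(gangs[idx], function(cg) cg@features))
    key <- paste(tab$genome_id, tab$feature_id, sep = "\r")
    agg <- tapply(tab$is_seed, key, any)
    tab <- tab[!duplicated(key), , drop = FALSE]
    tab$is_seed <- as.logical(agg[paste(tab$genome_id, tab$feature_id,
                                        sep = "\r")])
    tab <- tab[order(tab$genome_id, tab$contig_id, tab$start,
                     tab$feature_id), , drop = FALSE]
    rownames(tab) <- NULL
    cl <- sort(unique(tab$cluster_id[!is.na(tab$cluster_id)]))
    new("GeneGang", gangId = NA_character_, clusterIds = cl,
        features = tab, ruliness = numeric(), nGenomes = NA_integer_,
        flags = character())
  })
  ## canonical order for order-invariance: by sorted cluster-id signature
  sig <- vapply(out, function(g) paste(g@clusterIds, collapse = "|"),
                character(1))
  unname(out[order(sig)])
}

#' Paralog correction of gene gangs
#'
#' Repairs omissions caused by excluding large clusters from seeding: for
#' each gang, every genome is scanned around every member feature for
#' non-member features within the collinearity window whose cluster id is
#' already a gang cluster id. If such edge paralogs of a cluster are found
#' in at least `paralogCorrectionThreshold` genomes, they are admitted to
#' the gang (and its groupings). Features already belonging to another
#' gang are never moved; collisions are reported via a gang flag. A single
#' pass is run.
#'
#' @param gangs list of [GeneGang-class] objects (disjoint).
#' @param gs the parent [GenomeSet-class].
#' @param params a [GangParams-class].
#' @return the corrected list of [GeneGang-class] objects.
#' @export
paralogCorrection <- function(gangs, gs, params = GangParams()) {
  if (!length(gangs)) return(gangs)
  memberKey <- function(g) paste(g@features$genome_id,
                                 g@features$feature_id, sep = "\r")
  allMembers <- unlist(lapply(gangs, memberKey), use.names = FALSE)

  lapply(gangs, function(gang) {
    own <- memberKey(gang)
    othersMembers <- setdiff(allMembers, own)
    cand <- list()
    for (g in gs@genomes) {
      ft <- g@features
      memRows <- which(ft$feature_id %in%
                         gang@features$feature_id[
                           gang@features$genome_id == g@genomeId])
      if (!length(memRows)) next
      win <- .windowMembers(ft, memRows, params@maxGenomicDistance)
      win <- setdiff(win, memRows)
      if (!length(win)) next
      hit <- win[!is.na(ft$cluster_id[win]) &
                   ft$cluster_id[win] %in% gang@clusterIds]
      if (length(hit))
        cand[[g@genomeId]] <- cbind(genome_id = g@genomeId,
                                    ft[hit, , drop = FALSE],
                                    stringsAsFactors = FALSE)
    }
    if (!length(cand)) return(gang)
    ctab <- do.call(rbind, cand)
    nGen <- vapply(split(ctab$genome_id, ctab$cluster_id),
                   function(v) length(unique(v)), numeric(1))
    admitCl <- names(nGen)[nGen >= params@paralogCorrectionThreshold]
    add <- ctab[ctab$cluster_id %in% admitCl, , drop = FALSE]
    if (!nrow(add)) return(gang)
    key <- paste(add$genome_id, add$feature_id, sep = "\r")
    stolen <- key %in% othersMembers
    if (any(stolen)) {
      gang@flags <- unique(c(gang@flags, "paralog_collision"))
      add <- add[!stolen, , drop = FALSE]
    }
    if (!nrow(add)) return(gang)
    add$is_seed <- FALSE
    tab <- rbind(gang@features, add[, .GANG_COLS, drop = FALSE])
    tab <- tab[!duplicated(paste(tab$genome_id, tab$feature_id,
                                 sep = "\r")), , drop = FALSE]
    tab <- tab[order(tab$genome_id, tab$contig_id, tab$start,
                     tab$feature_id), , drop = FALSE]
    rownames(tab) <- NULL
    gang@features <- tab
    gang@clusterIds <- sort(unique(tab$cluster_id[!is.na(tab$cluster_id)]))
    gang
  })
}

#' Final filter on gene gangs
#'
#' Keeps gangs with at least `minGangClusters` gang cluster ids and at
#' least one member feature in every genome of the set.
#'
#' @param gangs list of [GeneGang-class] objects.
#' @param gs the parent [GenomeSet-class].
#' @param params a [GangParams-class].
#' @return the filtered list.
#' @export
finalFilter <- function(gangs, gs, params = GangParams()) {
  ids <- genomeIds(gs)
  keep <- vapply(gangs, function(g) {
    length(g@clusterIds) >= params@minGangClusters &&
      all(ids %in% g@features$genome_id)
  }, logical(1))
  gangs[keep]
}

#' Per-cluster ruliness of a gene gang
#'
#' The ruliness of a gang cluster id is the proportion of genomes that
#' contain at least one member feature with that cluster id. A gang's
#' ruliness is the minimum over its cluster ids: a "ruly" gang (ruliness
#' 1.00) has every cluster represented in every genome.
#'
#' @param gang a [GeneGang-class].
#' @param gs the parent [GenomeSet-class].
#' @return named numeric vector of per-cluster fractions.
#' @export
computeRuliness <- function(gang, gs) {
  n <- nGenomes(gs)
  tab <- gang@features
  tab <- tab[!is.na(tab$cluster_id) & tab$cluster_id %in% gang@clusterIds, ,
             drop = FALSE]
  prev <- vapply(split(tab$genome_id, tab$cluster_id),
                 function(v) length(unique(v)), numeric(1))
  out <- stats::setNames(rep(0, length(gang@clusterIds)), gang@clusterIds)
  out[names(prev)] <- prev / n
  out
}

#' Ruliness filter on a gene gang
#'
#' Removes all cluster ids (and their member features) whose ruliness is
#' below the threshold. A threshold of 1.00 yields the strict view (only
#' perfectly conserved clusters); a threshold of 0 is the identity
#' (unruly view). If filtering leaves fewer than `minGangClusters`
#' clusters, the gang is flagged `"degenerate"` and retained with a
#' warning.
#'
#' @param gang a [GeneGang-class] with ruliness computed.
#' @param threshold ruliness threshold in `[0, 1]`.
#' @param params a [GangParams-class] (for `minGangClusters`).
#' @return the filtered [GeneGang-class].
#' @export
rulinessFilter <- function(gang, threshold, params = GangParams()) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!length(gang@ruliness))
    .stopf("gang '%s' has no ruliness values; run computeRuliness first",
           gang@gangId)
  keepCl <- names(gang@ruliness)[gang@ruliness >= threshold - 1e-12]
  dropCl <- setdiff(gang@clusterIds, keepCl)
  if (!length(dropCl)) return(gang)
  tab <- gang@features
  tab <- tab[!(tab$cluster_id %in% dropCl), , drop = FALSE]
  rownames(tab) <- NULL
  gang@features <- tab
  gang@clusterIds <- sort(keepCl)
  gang@ruliness <- gang@ruliness[sort(keepCl)]
  if (length(gang@clusterIds) < params@minGangClusters) {
    gang@flags <- unique(c(gang@flags, "degenerate"))
    .warnf("gang '%s': ruliness filter %.2f left %d cluster(s), below the minimum of %d",
           gang@gangId, threshold, length(gang@clusterIds),
           params@minGangClusters)
  }
  gang
}

#' Detect gene gangs in a genome set
#'
#' The full pipeline: classify clusters, build genomic groupings and
#' cluster gangs from the seed clusters, apply the prevalence filter,
#' merge overlapping cluster gangs into disjoint gene gangs, run the
#' paralog correction, apply the final filter (at least
#' `minGangClusters` cluster ids and coverage of every genome), compute
#' ruliness, and optionally apply a ruliness filter. Deterministic given
#' inputs and parameters; gang ids are assigned in order of the gangs'
#' minimal genomic coordinate in the first genome (ties by cluster-id
#' signature).
#'
#' @param gs a [GenomeSet-class] with clusters attached.
#' @param params a [GangParams-class].
#' @param rulinessThreshold optional ruliness filter applied to the final
#'   gangs (default `NULL`: no filter, the "unruly" view; `1.0` gives the
#'   strict view).
#' @return list of [GeneGang-class] objects.
#' @export
detectGeneGangs <- function(gs, params = GangParams(),
                            rulinessThreshold = NULL) {
  if (!nGenomes(gs)) return(list())
  cl <- classifyClusters(gs, params)
  if (!length(cl$seed)) return(list())
  cgs <- buildClusterGangs(gs, cl$seed, params)
  cgs <- prevalenceFilter(cgs, params)
  gangs <- mergeToGeneGangs(cgs)
  if (length(gangs) == 1L && length(cgs) > 1L) {
    nCl <- length(unique(unlist(lapply(cgs, function(x) x@seedCluster))))
    if (length(gangs[[1L]]@clusterIds) >= 0.8 * nCl)
      .warnf(paste("merging converged to a single all-encompassing gang;",
                   "consider recalibrating maxGenomicDistance /",
                   "minGenomePrevalence to the collinear similarity of",
                   "these genomes"))
  }
  gangs <- paralogCorrection(gangs, gs, params)
  gangs <- finalFilter(gangs, gs, params)
  gangs <- lapply(gangs, function(g) {
    g@ruliness <- computeRuliness(g, gs)
    g@nGenomes <- as.integer(nGenomes(gs))
    g
  })
  if (!length(gangs)) return(list())

  ## stable ids: position of the gang in the first genome, then signature
  g1 <- genomeIds(gs)[1L]
  minPos <- vapply(gangs, function(g) {
    here <- g@features[g@features$genome_id == g1, , drop = FALSE]
    if (nrow(here)) min(here$start) else Inf
  }, numeric(1))
  sig <- vapply(gangs, function(g) paste(g@clusterIds, collapse = "|"),
                character(1))
  gangs <- gangs[order(minPos, sig)]
  gangs <- lapply(seq_along(gangs), function(i) {
    g <- gangs[[i]]
    g@gangId <- sprintf("gang_%02d", i)
    g
  })
  if (!is.null(rulinessThreshold))
    gangs <- lapply(gangs, rulinessFilter, threshold = rulinessThreshold,
                    params = params)
  gangs
}
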