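#' Synthetic genome-set configuration
#'
#' Convenience constructor for [SimConfig-class]; any slot can be
#' overridden by name, the rest keep their defaults.
#'
#' @param ... slot values, e.g. `nGenomes = 10`, `shuffleIntensity = 100`.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(...) {
  args <- list(...)
  intSlots <- c("nGenomes", "nGenesRange", "nCoreClusters",
                "plantedGangSizes", "largeFamilies")
  for (s in intersect(names(args), intSlots)) {
    nm <- names(args[[s]])
    args[[s]] <- as.integer(args[[s]])
    names(args[[s]]) <- nm
  }
  do.call(new, c(list("SimConfig"), args))
}

## Ancestor gene-unit table: one row per gene slot, in genomic order.
## Columns: cluster_id, type (core/gang/large/accessory), gang (index or
## NA), length, strand, gap_after.
.buildAncestor <- function(cfg) {
  sizes <- cfg@plantedGangSizes
  nGangGenes <- sum(sizes)
  coreLeft <- cfg@nCoreClusters - nGangGenes
  nPairs <- coreLeft %/% 2L
  nSingle <- coreLeft %% 2L

  coreIds <- sprintf("C%04d", seq_len(cfg@nCoreClusters))
  gangIds <- if (length(sizes))
    split(coreIds[seq_len(nGangGenes)],
          rep(seq_along(sizes), sizes)) else list()
  rest <- if (nGangGenes > 0L) coreIds[-seq_len(nGangGenes)] else coreIds
  blocks <- list()
  for (i in seq_along(gangIds))
    blocks[[length(blocks) + 1L]] <-
      list(ids = gangIds[[i]], type = "gang", gang = i)
  if (nPairs > 0L) for (i in seq_len(nPairs))
    blocks[[length(blocks) + 1L]] <-
      list(ids = rest[c(2L * i - 1L, 2L * i)], type = "core", gang = NA)
  if (nSingle)
    blocks[[length(blocks) + 1L]] <-
      list(ids = rest[coreLeft], type = "core", gang = NA)
  for (lf in names(cfg@largeFamilies)) {
    nSlots <- max(2L, round(cfg@largeFamilies[[lf]] / cfg@nGenomes))
    for (k in seq_len(nSlots))
      blocks[[length(blocks) + 1L]] <-
        list(ids = lf, type = "large", gang = NA)
  }
  blocks <- blocks[sample.int(length(blocks))]

  nGenes <- sample(seq(cfg@nGenesRange[1L], cfg@nGenesRange[2L]), 1L)
  nBlockGenes <- sum(vapply(blocks, function(b) length(b$ids), integer(1)))
  nAcc <- max(0L, nGenes - nBlockGenes)
  accPerRegion <- as.vector(stats::rmultinom(
    1L, nAcc, rep(1, length(blocks) + 1L)))

  rows <- list()
  accN <- 0L
  pushAcc <- function(k) {
    for (i in seq_len(k)) {
      accN <<- accN + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        cluster_id = sprintf("A%04d", accN), type = "accessory",
        gang = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  pushAcc(accPerRegion[1L])
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    for (id in blk$ids)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = id, type = blk$type,
        gang = if (is.na(blk$gang)) NA_integer_ else as.integer(blk$gang),
        stringsAsFactors = FALSE)
    pushAcc(accPerRegion[b + 1L])
  }
  anc <- do.call(rbind, rows)
  n <- nrow(anc)
  anc$length <- round(stats::runif(n, cfg@geneLengthRange[1L],
                                   cfg@geneLengthRange[2L]))
  anc$strand <- sample(c("+", "-"), n, replace = TRUE)
  anc$gap_after <- round(stats::runif(n, cfg@gapRange[1L], cfg@gapRange[2L]))

  ## spacing pass: inflate gaps so that consecutive conserved genes
  ## (core/gang/large) in different blocks keep a center-to-center
  ## distance above the planted-gang separation rules
  conserved <- which(anc$type != "accessory")
  if (length(conserved) > 1L) {
    for (k in seq_len(length(conserved) - 1L)) {
      i <- conserved[k]; j <- conserved[k + 1L]
      sameGang <- !is.na(anc$gang[i]) && !is.na(anc$gang[j]) &&
        anc$gang[i] == anc$gang[j]
      samePair <- anc$type[i] == "core" && anc$type[j] == "core" &&
        j == i + 1L &&
        .samePairBlock(anc$cluster_id[i], anc$cluster_id[j], blocks)
      if (sameGang || samePair) next
      req <- if (!is.na(anc$gang[i]) || !is.na(anc$gang[j]))
        cfg@gangSpacingBp else cfg@gangSpacingBp / 2 + 500
      span <- sum(anc$length[i:j]) - anc$length[i] / 2 -
        anc$length[j] / 2 + sum(anc$gap_after[i:(j - 1L)])
      if (span < req)
        anc$gap_after[j - 1L] <- anc$gap_after[j - 1L] + ceiling(req - span)
    }
  }
  rownames(anc) <- NULL
  attr(anc, "gangClusters") <- gangIds
  anc
}

.samePairBlock <- function(a, b, blocks) {
  for (blk in blocks)
    if (blk$type == "core" && length(blk$ids) == 2L &&
        all(c(a, b) %in% blk$ids)) return(TRUE)
  FALSE
}

## One rearranged genome from the ancestor unit table. Deletions keep the
## deleted gene's footprint as intergenic spacer so that distances among
## the remaining genes are unchanged (pseudogenization rather than
## contraction). Returns list(units = reordered table with 'present'
## column, events = data.frame).
.evolveGenome <- function(anc, cfg, genomeIdx) {
  units <- anc
  units$present <- TRUE
  events <- list()

  ## accessory presence: per-cluster genome subsets are decided globally
  ## (in .simulatePresence); here we only apply the mask
  ## gang disruption
  gangIdx <- unique(units$gang[!is.na(units$gang)])
  for (g in gangIdx) {
    if (cfg@gangDisruptionRate > 0 &&
        stats::runif(1L) < cfg@gangDisruptionRate) {
      mem <- which(!is.na(units$gang) & units$gang == g & units$present)
      drop <- mem[sample.int(length(mem), 1L)]
      units$present[drop] <- FALSE
      events[[length(events) + 1L]] <- data.frame(
        type = "deletion", block_start = drop, block_end = drop,
        detail = sprintf("gang %d member %s", g, units$cluster_id[drop]),
        stringsAsFactors = FALSE)
    }
  }

  nEv <- stats::rpois(1L, cfg@shuffleIntensity)
  for (e in seq_len(nEv)) {
    type <- sample(c("inversion", "translocation"), 1L)
    done <- FALSE
    for (try in seq_len(50L)) {
      n <- nrow(units)
      i <- sample.int(n, 1L)
      L <- sample(2:25, 1L)
      j <- min(n, i + L - 1L)
      if (.splitsGang(units$gang, i, j)) next
      if (type == "inversion") {
        blk <- units[j:i, , drop = FALSE]
        blk$strand <- ifelse(blk$strand == "+", "-", "+")
        ## the inverted segment spans genes i..j with their internal gaps;
        ## internal gaps reverse with the genes, the right-boundary gap
        ## (after gene j) stays at the boundary
        if (j > i)
          blk$gap_after <- c(rev(units$gap_after[i:(j - 1L)]),
                             units$gap_after[j])
        units <- rbind(if (i > 1L) units[seq_len(i - 1L), ] else NULL,
                       blk,
                       if (j < n) units[(j + 1L):n, ] else NULL)
      } else {
        blk <- units[i:j, , drop = FALSE]
        rest <- units[-(i:j), , drop = FALSE]
        repeat {
          p <- sample.int(nrow(rest) + 1L, 1L) - 1L   # insert after p
          if (!.insertionSplitsGang(rest$gang, p)) break
        }
        units <- rbind(if (p > 0L) rest[seq_len(p), ] else NULL,
                       blk,
                       if (p < nrow(rest)) rest[(p + 1L):nrow(rest), ] else NULL)
      }
      events[[length(events) + 1L]] <- data.frame(
        type = type, block_start = i, block_end = j,
        detail = sprintf("%d units", j - i + 1L), stringsAsFactors = FALSE)
      done <- TRUE
      break
    }
    if (!done) next
  }
  rownames(units) <- NULL
  list(units = units,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(type = character(), block_start = integer(),
                    block_end = integer(), detail = character()))
}

.splitsGang <- function(gang, i, j) {
  inside <- gang[i:j]
  for (g in unique(inside[!is.na(inside)])) {
    tot <- sum(gang == g, na.rm = TRUE)
    if (sum(inside == g, na.rm = TRUE) != tot) return(TRUE)
  }
  FALSE
}

.insertionSplitsGang <- function(gang, p) {
  if (p < 1L || p >= length(gang)) return(FALSE)
  !is.na(gang[p]) && !is.na(gang[p + 1L]) && gang[p] == gang[p + 1L]
}

## Lay a unit table out on one linear contig; deleted units become spacer.
.layoutGenome <- function(units, genomeId) {
  n <- nrow(units)
  starts <- ends <- numeric(n)
  cursor <- 0
  for (i in seq_len(n)) {
    starts[i] <- cursor + 1
    ends[i] <- cursor + units$length[i]
    cursor <- ends[i] + units$gap_after[i]
  }
  keep <- units$present
  m <- sum(keep)
  ft <- data.frame(
    feature_id = sprintf("%s_%04d", genomeId, seq_len(m)),
    contig_id = "chr",
    start = starts[keep], end = ends[keep],
    strand = units$strand[keep],
    cluster_id = units$cluster_id[keep],
    product = NA_character_,
    stringsAsFactors = FALSE)
  contig <- data.frame(contig_id = "chr", length = cursor + 100)
  g <- AnnotatedGenome(genomeId, features = ft, contigs = contig)
  idx <- which(keep)
  map <- data.frame(feature_id = ft$feature_id,
                    cluster_id = units$cluster_id[idx],
                    gang = units$gang[idx], stringsAsFactors = FALSE)
  list(genome = g, map = map)
}

#' Simulate a genome set with planted gene gangs
#'
#' Builds a single ancestor genome — planted gangs on consecutive gene
#' slots, remaining core clusters as isolated singletons or pairs
#' separated from other conserved genes by more than the collinearity
#' window, large paralog families, and accessory genes filling the gaps —
#' then derives each genome by applying accessory presence/absence,
#' optional gang disruption, and Poisson-many block inversions and
#' translocations that never split a planted gang. Deletions leave the
#' deleted gene's footprint in place, so pairwise distances among
#' surviving genes are unaffected. A star phylogeny with branch lengths
#' proportional to the number of applied events is returned alongside the
#' planted-truth manifest. Deterministic for a fixed seed.
#'
#' @param cfg a [SimConfig-class].
#' @param seed integer RNG seed.
#' @return list with `genomes` (a [GenomeSet-class]), `truth`
#'   (a [SyntheticTruth-class]) and `tree` (an [ape::phylo]).
#' @export
simulateGenomeSet <- function(cfg = SimConfig(), seed = 1L) {
  set.seed(seed)
  anc <- .buildAncestor(cfg)
  gangClusters <- attr(anc, "gangClusters")
  nG <- cfg@nGenomes
  gids <- sprintf("G%02d", seq_len(nG))

  ## accessory presence: each accessory cluster present in a bounded
  ## fraction of genomes
  accCl <- unique(anc$cluster_id[anc$type == "accessory"])
  lo <- max(1L, floor(cfg@accessoryPrevalenceRange[1L] * nG))
  hi <- max(lo, floor(cfg@accessoryPrevalenceRange[2L] * nG))
  presence <- lapply(accCl, function(cl) {
    m <- if (hi > lo) sample(lo:hi, 1L) else lo
    sort(sample.int(nG, m))
  })
  names(presence) <- accCl

  genomes <- vector("list", nG)
  evAll <- list()
  gangFeat <- list()
  nEvents <- integer(nG)
  for (k in seq_len(nG)) {
    ev <- .evolveGenome(anc, cfg, k)
    units <- ev$units
    isAcc <- units$type == "accessory"
    absent <- isAcc &
      !vapply(units$cluster_id, function(cl)
        !is.null(presence[[cl]]) && k %in% presence[[cl]], logical(1))
    units$present <- units$present & !absent
    lay <- .layoutGenome(units, gids[k])
    genomes[[k]] <- lay$genome
    if (nrow(ev$events))
      evAll[[k]] <- cbind(genome_id = gids[k], ev$events,
                          stringsAsFactors = FALSE)
    nEvents[k] <- sum(ev$events$type %in% c("inversion", "translocation"))
    gm <- lay$map[!is.na(lay$map$gang), , drop = FALSE]
    if (nrow(gm))
      gangFeat[[k]] <- data.frame(gang = gm$gang, genome_id = gids[k],
                                  feature_id = gm$feature_id,
                                  cluster_id = gm$cluster_id,
                                  stringsAsFactors = FALSE)
  }
  gs <- GenomeSet(genomes)
  events <- if (length(evAll)) do.call(rbind, evAll) else
    data.frame(genome_id = character(), type = character(),
               block_start = integer(), block_end = integer(),
               detail = character())
  rownames(events) <- NULL
  gf <- if (length(gangFeat)) do.call(rbind, gangFeat) else
    data.frame(gang = integer(), genome_id = character(),
               feature_id = character(), cluster_id = character())
  gf <- gf[order(gf$gang, gf$genome_id, gf$feature_id), , drop = FALSE]
  rownames(gf) <- NULL
  truth <- new("SyntheticTruth", gangClusters = gangClusters,
               gangFeatures = gf, events = events, config = cfg)
  nwk <- paste0("(", paste(sprintf("%s:%.6f", gids,
                                   0.001 + 0.02 * nEvents),
                           collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  list(genomes = gs, truth = truth, tree = tree)
}

#' Degrade the ruliness of one cluster
#'
#' Deletes all features of a cluster from `k` randomly chosen genomes (of
#' those containing it), so that the cluster's ruliness inside any gang
#' containing it becomes `(n - k) / n` exactly. The truth manifest, when
#' given, is updated with deletion events.
#'
#' @param gs a [GenomeSet-class].
#' @param clusterId the cluster to degrade.
#' @param k number of genomes to delete it from.
#' @param seed RNG seed for choosing the genomes.
#' @param truth optional [SyntheticTruth-class] to update.
#' @return list with `genomes` (modified set) and `truth`.
#' @export
degradeRuliness <- function(gs, clusterId, k, seed = 1L, truth = NULL) {
  holders <- names(Filter(function(g)
    any(!is.na(g@features$cluster_id) &
          g@features$cluster_id == clusterId), gs@genomes))
  if (!length(holders)) .stopf("cluster '%s' not found", clusterId)
  if (k >= length(holders))
    .stopf("k = %d would remove cluster '%s' from all %d genomes carrying it",
           k, clusterId, length(holders))
  if (k == 0L) return(list(genomes = gs, truth = truth))
  set.seed(seed)
  victims <- sample(holders, k)
  newGenomes <- lapply(gs@genomes, function(g) {
    if (!(g@genomeId %in% victims)) return(g)
    ft <- g@features
    drop <- !is.na(ft$cluster_id) & ft$cluster_id == clusterId
    g@features <- ft[!drop, , drop = FALSE]
    rownames(g@features) <- NULL
    g
  })
  out <- GenomeSet(newGenomes)
  if (!is.null(truth)) {
    add <- data.frame(genome_id = victims, type = "degrade_deletion",
                      block_start = NA_integer_, block_end = NA_integer_,
                      detail = clusterId, stringsAsFactors = FALSE)
    truth@events <- rbind(truth@events, add)
    keep <- !(truth@gangFeatures$cluster_id == clusterId &
                truth@gangFeatures$genome_id %in% victims)
    truth@gangFeatures <- truth@gangFeatures[keep, , drop = FALSE]
  }
  list(genomes = out, truth = truth)
}

#' Write a simulated genome set to disk
#'
#' One GFF3 + FASTA pair per genome, a `clusters.tsv` homology table, a
#' `tree.nwk` when a tree is given, and a `truth.json` when a truth
#' manifest is given. Re-reading the files through [readGFF3Genome()] and
#' [readClusterTable()] reproduces the in-memory set.
#'
#' @param gs a [GenomeSet-class].
#' @param dir output directory (created if needed).
#' @param truth optional [SyntheticTruth-class].
#' @param tree optional [ape::phylo].
#' @return `dir`, invisibly.
#' @export
writeGenomeSet <- function(gs, dir, truth = NULL, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in gs@genomes)
    writeGFF3Genome(g, file.path(dir, paste0(g@genomeId, ".gff3")),
                    file.path(dir, paste0(g@genomeId, ".fasta")))
  ft <- features(gs)
  tab <- ft[!is.na(ft$cluster_id),
            c("genome_id", "feature_id", "cluster_id"), drop = FALSE]
  utils::write.table(tab, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(tree))
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(gang_clusters = truth@gangClusters,
           gang_features = truth@gangFeatures,
           events = truth@events),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a genome set written by [writeGenomeSet()]
#'
#' @param dir directory containing `<genome>.gff3` / `<genome>.fasta`
#'   pairs and `clusters.tsv`.
#' @return a [GenomeSet-class].
#' @export
readGenomeSetDir <- function(dir) {
  gffs <- sort(list.files(dir, pattern = "\\.gff3?$", full.names = TRUE))
  genomes <- lapply(gffs, function(p) {
    fa <- sub("\\.gff3?$", ".fasta", p)
    if (!file.exists(fa)) .stopf("no FASTA next to '%s'", p)
    readGFF3Genome(p, fa)
  })
  gs <- GenomeSet(genomes)
  ctab <- file.path(dir, "clusters.tsv")
  if (file.exists(ctab)) gs <- readClusterTable(ctab, gs)
  gs
}
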