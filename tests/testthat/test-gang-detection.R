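test_that("large-cluster classification uses a strict > 80 boundary", {
  # one cluster with 81 members, one with exactly 80, one small
  mk <- function(k, cl) quickGenome(sprintf("g%02d", k),
                                    centers = seq(1000, by = 8000,
                                                  length.out = length(cl)),
                                    clusters = cl)
  # spread 81 copies of L1 and 80 of L2 over 41 genomes
  counts <- data.frame(genome = rep(sprintf("g%02d", 1:41), length.out = 81))
  genomes <- lapply(1:41, function(k) {
    nL1 <- sum(counts$genome == sprintf("g%02d", k))
    nL2 <- if (k <= 39) 2 else if (k == 40) 2 else 0   # 80 total
    cl <- c(rep("L1", nL1), rep("L2", nL2), "small")
    mk(k, cl)
  })
  gs <- GenomeSet(genomes)
  ft <- features(gs)
  expect_equal(sum(ft$cluster_id == "L1", na.rm = TRUE), 81L)
  expect_equal(sum(ft$cluster_id == "L2", na.rm = TRUE), 80L)
  cls <- classifyClusters(gs)
  expect_equal(cls$large, "L1")
  expect_setequal(cls$seed, c("L2", "small"))

  # random sizes: partition equals direct counting
  set.seed(13)
  sizes <- table(sample(sprintf("c%02d", 1:30), 2000, replace = TRUE))
  g1 <- quickGenome("one", seq(1000, by = 5000, length.out = 2000),
                    clusters = rep(names(sizes), sizes))
  cls2 <- classifyClusters(GenomeSet(list(g1)))
  expect_setequal(cls2$large, names(sizes)[sizes > 80])
  expect_setequal(cls2$seed, names(sizes)[sizes <= 80])
})

test_that("groupings include neighbors at exactly 3500 bp and exclude 3501", {
  g <- quickGenome("g", c(7000, 10000, 13500, 13501, 25000),
                   clusters = c("n1", "seed", "n2", "n3", "far"))
  grp <- buildGrouping(g, "seed")
  expect_setequal(grp$cluster_id, c("n1", "seed", "n2"))   # 3500 in, 3501 out
  expect_equal(grp$is_seed, grp$cluster_id == "seed")

  # seed with no neighbors in range stands alone
  g2 <- quickGenome("g2", c(1000, 20000), clusters = c("seed", "far"))
  expect_equal(buildGrouping(g2, "seed")$cluster_id, "seed")

  # absent seed gives NULL
  expect_null(buildGrouping(g2, "ghost"))

  # window never crosses a contig break
  g3 <- quickGenome("g3", c(1000, 2000), clusters = c("seed", "near"),
                    contig = c("c1", "c2"))
  expect_equal(buildGrouping(g3, "seed")$cluster_id, "seed")
})

test_that("split genes contribute combined windows, matched by brute force", {
  centers <- c(2000, 5000, 6000, 9200, 14000)
  cl <- c("x", "seed", "seed", "y", "z")
  g <- quickGenome("g", centers, clusters = cl)
  grp <- buildGrouping(g, "seed")
  # brute force: any feature within 3500 of either seed center
  want <- vapply(centers, function(cen)
    any(abs(cen - c(5000, 6000)) <= 3500), logical(1))
  expect_setequal(grp$cluster_id, cl[want])
  expect_equal(sum(grp$is_seed), 2L)
})

test_that("cluster gangs compose per-genome groupings", {
  mk <- function(id, centers, cl) quickGenome(id, centers, clusters = cl)
  gs <- GenomeSet(list(
    mk("g1", c(1000, 3000, 20000), c("s", "b", "c")),
    mk("g2", c(5000, 7000, 40000), c("s", "b", "c")),
    mk("g3", c(1000, 9000), c("b", "c"))))        # seed absent
  cg <- buildClusterGangs(gs, "s")
  expect_length(cg, 1L)
  tab <- features(cg[["s"]])
  expect_setequal(unique(tab$genome_id), c("g1", "g2"))
  # oracle: per-genome buildGrouping calls
  for (gid in c("g1", "g2")) {
    want <- buildGrouping(genomes(gs)[[gid]], "s")
    got <- tab[tab$genome_id == gid, names(want)]
    rownames(got) <- NULL
    expect_equal(got, want)
  }
  # seed absent everywhere: dropped entirely
  expect_length(buildClusterGangs(gs, "ghost"), 0L)
})

test_that("prevalence filter keeps 34/41 seeds, drops 33/41, prunes rare members", {
  # seed at a fixed locus in `p` genomes, with a companion in all of them
  # and a sporadic bystander in only 5
  mkSet <- function(p) {
    genomes <- lapply(1:41, function(k) {
      id <- sprintf("g%02d", k)
      if (k <= p) {
        cl <- c("seed", "mate", if (k <= 5) "rare")
        quickGenome(id, c(10000, 12000, 13000)[seq_along(cl)], clusters = cl)
      } else quickGenome(id, 10000, clusters = "other")
    })
    GenomeSet(genomes)
  }
  gs34 <- mkSet(34)
  cg <- buildClusterGangs(gs34, "seed")
  kept <- prevalenceFilter(cg)
  expect_length(kept, 1L)
  expect_setequal(clusterIds(kept[[1]]), c("seed", "mate"))  # rare pruned
  expect_false("rare" %in% kept[[1]]@features$cluster_id)

  gs33 <- mkSet(33)
  expect_length(prevalenceFilter(buildClusterGangs(gs33, "seed")), 0L)

  # threshold 1 keeps everything including the rare member
  loose <- prevalenceFilter(cg, GangParams(minGenomePrevalence = 1))
  expect_true("rare" %in% clusterIds(loose[[1]]))
})

test_that("merging equals connected components of the cluster-overlap graph", {
  mkGang <- function(seed, clusters, genome = "g1") {
    n <- length(clusters)
    quickClusterGang(seed, data.frame(
      genome_id = genome,
      feature_id = paste0(seed, "_", seq_len(n)),
      cluster_id = clusters,
      center = seq(1000, by = 1000, length.out = n)))
  }
  # disjoint sets stay apart
  out <- mergeToGeneGangs(list(mkGang("A", c("A", "B")),
                               mkGang("C", c("C", "D"))))
  expect_length(out, 2L)
  # transitive overlap collapses to one gang
  out2 <- mergeToGeneGangs(list(mkGang("A", c("A", "B")),
                                mkGang("B", c("B", "C")),
                                mkGang("C", c("C", "D"))))
  expect_length(out2, 1L)
  expect_equal(clusterIds(out2[[1]]), c("A", "B", "C", "D"))

  # property: random instances vs an independently coded graph oracle
  set.seed(99)
  universe <- sprintf("K%02d", 1:20)
  for (rep in 1:25) {
    gangs <- lapply(1:12, function(i)
      mkGang(sprintf("S%02d", i),
             sample(universe, sample(1:4, 1)),
             genome = sample(c("g1", "g2"), 1)))
    got <- mergeToGeneGangs(gangs)
    # oracle: igraph components over the shared-cluster graph
    sets <- lapply(gangs, clusterIds)
    edges <- c()
    for (i in 1:11) for (j in (i + 1):12)
      if (length(intersect(sets[[i]], sets[[j]]))) edges <- c(edges, i, j)
    gr <- igraph::make_empty_graph(12, directed = FALSE)
    if (length(edges)) gr <- igraph::add_edges(gr, edges)
    comp <- igraph::components(gr)$membership
    wantSets <- lapply(split(seq_len(12), comp), function(idx)
      sort(unique(unlist(sets[idx]))))
    gotSets <- lapply(got, clusterIds)
    expect_setequal(vapply(wantSets, paste, character(1), collapse = ","),
                    vapply(gotSets, paste, character(1), collapse = ","))
  }

  # result is independent of input order
  gangs <- list(mkGang("A", c("A", "B")), mkGang("B", c("B", "C")),
                mkGang("Z", c("Y", "Z")))
  expect_equal(gangSignatures(mergeToGeneGangs(gangs)),
               gangSignatures(mergeToGeneGangs(rev(gangs))))
})

test_that("paralog correction admits edge paralogs above the genome threshold only", {
  # gang of clusters a,b in 20 genomes; a second copy of cluster b sits
  # 3 kb outside the grouping in `k` genomes
  mkCase <- function(k) {
    genomes <- lapply(1:20, function(i) {
      id <- sprintf("g%02d", i)
      centers <- c(10000, 12000)
      cl <- c("a", "b")
      if (i <= k) { centers <- c(centers, 15000); cl <- c(cl, "b") }
      quickGenome(id, centers, clusters = cl)
    })
    gs <- GenomeSet(genomes)
    gang <- quickGeneGang("gang_01", do.call(rbind, lapply(1:20, function(i)
      data.frame(genome_id = sprintf("g%02d", i),
                 feature_id = sprintf("g%02d_f%02d", i, 1:2),
                 cluster_id = c("a", "b"),
                 center = c(10000, 12000)))), nGenomes = 20)
    list(gs = gs, gang = gang)
  }
  p <- GangParams(paralogCorrectionThreshold = 15, minGenomePrevalence = 15)

  # found in 18 genomes: admitted, features join the groupings
  cs <- mkCase(18)
  out <- paralogCorrection(list(cs$gang), cs$gs, p)[[1]]
  expect_equal(sum(out@features$feature_id == "g01_f03"), 1L)
  expect_equal(nrow(out@features), 40 + 18)

  # found in only 3 genomes: not admitted
  cs2 <- mkCase(3)
  out2 <- paralogCorrection(list(cs2$gang), cs2$gs, p)[[1]]
  expect_equal(nrow(out2@features), 40L)

  # a feature owned by another gang is never stolen
  cs3 <- mkCase(18)
  thief <- quickGeneGang("gang_02", do.call(rbind, lapply(1:18, function(i)
    data.frame(genome_id = sprintf("g%02d", i),
               feature_id = sprintf("g%02d_f03", i),
               cluster_id = "b", center = 15000))), nGenomes = 20)
  both <- paralogCorrection(list(cs3$gang, thief), cs3$gs, p)
  expect_equal(nrow(both[[1]]@features), 40L)
  expect_true("paralog_collision" %in% gangFlags(both[[1]]))
})

test_that("final filter needs three clusters and full genome coverage", {
  gsIds <- GenomeSet(lapply(c("g1", "g2"), function(id)
    quickGenome(id, c(1000, 3000, 5000), clusters = c("a", "b", "c"))))
  full <- quickGeneGang("x", data.frame(
    genome_id = rep(c("g1", "g2"), each = 3),
    feature_id = paste0(rep(c("g1", "g2"), each = 3), "_f", 1:3),
    cluster_id = rep(c("a", "b", "c"), 2),
    center = rep(c(1000, 3000, 5000), 2)), nGenomes = 2)
  twoCl <- quickGeneGang("y", data.frame(
    genome_id = c("g1", "g2"), feature_id = c("g1_f1", "g2_f1"),
    cluster_id = c("a", "a"), center = c(1000, 1000)), nGenomes = 2)
  missing <- quickGeneGang("z", data.frame(
    genome_id = "g1", feature_id = paste0("g1_f", 1:3),
    cluster_id = c("a", "b", "c"), center = c(1000, 3000, 5000)),
    nGenomes = 2)
  kept <- finalFilter(list(full, twoCl, missing), gsIds)
  expect_length(kept, 1L)
  expect_equal(gangId(kept[[1]]), "x")
})

test_that("ruliness follows the worked three-cluster example", {
  # clusters <A, B, C> present in 10/10, 10/10 and 9/10 genomes
  n <- 10
  tab <- do.call(rbind, lapply(1:n, function(k) {
    cl <- c("A", "B", if (k < n) "C")
    data.frame(genome_id = sprintf("g%02d", k),
               feature_id = sprintf("g%02d_f%d", k, seq_along(cl)),
               cluster_id = cl,
               center = c(1000, 2500, 4000)[seq_along(cl)])
  }))
  gs <- GenomeSet(lapply(split(tab, tab$genome_id), function(sub)
    quickGenome(sub$genome_id[1], sub$center, clusters = sub$cluster_id)))
  # rebuild feature ids to match the set's own
  tab$feature_id <- unlist(lapply(split(tab, tab$genome_id), function(sub)
    sprintf("%s_f%02d", sub$genome_id[1], seq_len(nrow(sub)))))
  gang <- quickGeneGang("X", tab, nGenomes = n)
  r <- computeRuliness(gang, gs)
  expect_equal(unname(r[c("A", "B", "C")]), c(1.00, 1.00, 0.90))
  expect_equal(min(r), 0.90)   # the gang's ruliness

  gang@ruliness <- r
  expect_warning(strict <- rulinessFilter(gang, 1.00), "below the minimum")
  expect_equal(clusterIds(strict), c("A", "B"))
  expect_true("degenerate" %in% gangFlags(strict))
  expect_false("C" %in% strict@features$cluster_id)

  # threshold 0 is the identity
  expect_equal(clusterIds(rulinessFilter(gang, 0)), clusterIds(gang))

  # monotone shrinkage across a sweep of thresholds
  prev <- clusterIds(gang)
  for (th in c(0.5, 0.9, 0.95, 1)) {
    cur <- clusterIds(suppressWarnings(rulinessFilter(gang, th)))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("ruliness of a cluster in 34 of 41 genomes is 0.829", {
  tab <- do.call(rbind, lapply(1:41, function(k) {
    cl <- c("A", if (k <= 34) "B")
    data.frame(genome_id = sprintf("g%02d", k),
               feature_id = sprintf("g%02d_f%d", k, seq_along(cl)),
               cluster_id = cl, center = c(1000, 2500)[seq_along(cl)])
  }))
  gs <- GenomeSet(lapply(split(tab, tab$genome_id), function(sub)
    quickGenome(sub$genome_id[1], sub$center, clusters = sub$cluster_id)))
  gang <- quickGeneGang("X", tab, nGenomes = 41)
  r <- computeRuliness(gang, gs)
  expect_equal(unname(r["B"]), 34 / 41)
  expect_equal(round(unname(r["B"]), 3), 0.829)
})

test_that("detection is empty on an empty set and disjoint + order-invariant on simulations", {
  expect_length(detectGeneGangs(GenomeSet()), 0L)

  cfg <- SimConfig(nGenomes = 12, nGenesRange = c(110L, 130L),
                   nCoreClusters = 40L, plantedGangSizes = c(3L, 5L),
                   largeFamilies = c(LF1 = 30L))
  sim <- simulateGenomeSet(cfg, seed = 17)
  p <- GangParams(minGenomePrevalence = 10, largeClusterThreshold = 25)
  gangs <- detectGeneGangs(sim$genomes, p)
  expect_gte(length(gangs), 2L)

  # disjointness of member features, exhaustively
  keys <- lapply(gangs, function(g)
    paste(g@features$genome_id, g@features$feature_id))
  expect_equal(anyDuplicated(unlist(keys)), 0L)

  # ruliness bounds from the prevalence floor
  for (g in gangs)
    expect_true(all(ruliness(g) >= 10 / 12 - 1e-12 & ruliness(g) <= 1))

  # permuting genome order leaves gang memberships identical
  perm <- GenomeSet(rev(genomes(sim$genomes)))
  gangs2 <- detectGeneGangs(perm, p)
  expect_equal(gangSignatures(gangs), gangSignatures(gangs2))
})
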