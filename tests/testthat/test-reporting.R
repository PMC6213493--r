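# A hand-built three-genome set carrying one gang with controllable
# order/strand/alien structure per genome.
reportFixture <- function(orders = NULL, strandsOf = NULL, alien = NULL) {
  base <- c(a = 10000, b = 13000, c = 16000)
  if (is.null(orders))
    orders <- list(g1 = c("a", "b", "c"), g2 = c("a", "b", "c"),
                   g3 = c("a", "b", "c"))
  genomes <- lapply(names(orders), function(gid) {
    cl <- orders[[gid]]
    centers <- base[seq_along(cl)]
    strands <- if (!is.null(strandsOf) && gid %in% names(strandsOf))
      strandsOf[[gid]] else rep("+", length(cl))
    if (!is.null(alien) && gid %in% alien) {
      cl <- c(cl[1], "alienX", cl[-1])
      centers <- c(centers[1], centers[1] + 1500, centers[-1] + 1000)
      strands <- c(strands[1], "+", strands[-1])
    }
    quickGenome(gid, unname(centers), clusters = cl, strands = strands)
  })
  gs <- GenomeSet(genomes)
  tab <- do.call(rbind, lapply(genomes, function(g) {
    ft <- features(g)
    ft <- ft[ft$cluster_id %in% c("a", "b", "c"), , drop = FALSE]
    data.frame(genome_id = genomeId(g), feature_id = ft$feature_id,
               cluster_id = ft$cluster_id, start = ft$start, end = ft$end,
               contig_id = ft$contig_id, strand = ft$strand)
  }))
  gang <- quickGeneGang("gang_01", tab, nGenomes = length(genomes))
  list(gs = gs, gang = gang)
}

test_that("consensus order is the modal arrangement with reversal identified", {
  fx <- reportFixture()
  expect_equal(consensusOrder(fx$gang), c("a", "b", "c"))

  # 3 genomes a-b-c, 1 genome c-b-a: reversal counts toward the same mode
  fx2 <- reportFixture(orders = list(g1 = c("a", "b", "c"),
                                     g2 = c("a", "b", "c"),
                                     g3 = c("a", "b", "c"),
                                     g4 = c("c", "b", "a")))
  expect_equal(consensusOrder(fx2$gang), c("a", "b", "c"))

  # random orders: mode matches a counting-dictionary oracle
  set.seed(42)
  perms <- list(c("a", "b", "c"), c("b", "a", "c"), c("a", "c", "b"))
  draws <- sample(1:3, 9, replace = TRUE)
  orders <- stats::setNames(perms[draws], sprintf("g%02d", 1:9))
  fx3 <- reportFixture(orders = orders)
  keys <- vapply(orders, function(o) {
    f <- paste(o, collapse = "|"); r <- paste(rev(o), collapse = "|")
    min(f, r)
  }, character(1))
  modal <- names(which.max(table(keys)))
  got <- consensusOrder(fx3$gang)
  gotKey <- min(paste(got, collapse = "|"), paste(rev(got), collapse = "|"))
  expect_equal(gotKey, modal)
})

test_that("a perfectly conserved gang scores (n, n, n, 0)", {
  fx <- reportFixture()
  tm <- topologyMetrics(fx$gang, fx$gs)
  expect_equal(tm$max_members, 3L)
  expect_equal(tm$consensus_members, 3L)
  expect_equal(tm$n_ruly_genomes, 3)
  expect_equal(tm$n_syntenic_genomes, 3)
  expect_equal(tm$n_strand_conserved_genomes, 3)
  expect_equal(tm$n_infiltrated_genomes, 0)
})

test_that("order scrambles, strand flips and aliens are each counted", {
  # one genome with b,c swapped: loses synteny (and thus strandedness)
  fx <- reportFixture(orders = list(g1 = c("a", "b", "c"),
                                    g2 = c("a", "b", "c"),
                                    g3 = c("a", "c", "b")))
  tm <- topologyMetrics(fx$gang, fx$gs)
  expect_equal(tm$n_ruly_genomes, 3)          # content still complete
  expect_equal(tm$n_syntenic_genomes, 2)
  expect_equal(tm$n_strand_conserved_genomes, 2)

  # one genome with a single member on the other strand
  fx2 <- reportFixture(strandsOf = list(g3 = c("+", "-", "+")))
  tm2 <- topologyMetrics(fx2$gang, fx2$gs)
  expect_equal(tm2$n_syntenic_genomes, 3)
  expect_equal(tm2$n_strand_conserved_genomes, 2)

  # a fully reversed genome (order and strands) still matches consensus
  fx3 <- reportFixture(orders = list(g1 = c("a", "b", "c"),
                                     g2 = c("a", "b", "c"),
                                     g3 = c("c", "b", "a")),
                       strandsOf = list(g3 = c("-", "-", "-")))
  tm3 <- topologyMetrics(fx3$gang, fx3$gs)
  expect_equal(tm3$n_syntenic_genomes, 3)
  expect_equal(tm3$n_strand_conserved_genomes, 3)

  # an alien gene inside the span of one genome
  fx4 <- reportFixture(alien = "g2")
  tm4 <- topologyMetrics(fx4$gang, fx4$gs)
  expect_equal(tm4$n_infiltrated_genomes, 1)
})

test_that("topology counts are invariant under coordinate reversal", {
  fx <- reportFixture(orders = list(g1 = c("a", "b", "c"),
                                    g2 = c("b", "a", "c"),
                                    g3 = c("a", "b", "c")),
                      strandsOf = list(g2 = c("-", "+", "+")),
                      alien = "g1")
  tm <- topologyMetrics(fx$gang, fx$gs)

  flipGenome <- function(g) {
    L <- contigs(g)$length[1]
    ft <- features(g)
    newStart <- L - ft$end + 1
    newEnd <- L - ft$start + 1
    ft$start <- newStart; ft$end <- newEnd
    ft$strand <- ifelse(ft$strand == "+", "-", "+")
    AnnotatedGenome(genomeId(g), features = ft, contigs = contigs(g))
  }
  gsR <- GenomeSet(lapply(genomes(fx$gs), flipGenome))
  tabR <- features(gsR)
  tabR <- tabR[tabR$cluster_id %in% c("a", "b", "c"), , drop = FALSE]
  gangR <- quickGeneGang("gang_01", tabR, nGenomes = nGenomes(gsR))
  tmR <- topologyMetrics(gangR, gsR)
  for (f in c("max_members", "consensus_members", "n_ruly_genomes",
              "n_syntenic_genomes", "n_strand_conserved_genomes",
              "n_infiltrated_genomes"))
    expect_equal(tmR[[f]], tm[[f]], info = f)
})

test_that("dot plots put identical genomes on the diagonal and flag inversions", {
  g1 <- quickGenome("g1", c(1000, 5000, 9000), clusters = c("a", "b", "c"))
  g2 <- quickGenome("g2", c(1000, 5000, 9000), clusters = c("a", "b", "c"))
  dp <- dotPlotData(g1, g2)
  expect_equal(dp$center_a, dp$center_b)
  expect_true(all(dp$same_strand))

  # self-comparison with a paralog: diagonal plus off-diagonal points
  gp <- quickGenome("gp", c(1000, 5000, 20000), clusters = c("a", "b", "a"))
  dps <- dotPlotData(gp, gp)
  expect_equal(sum(dps$center_a == dps$center_b), 3L)
  expect_equal(sum(dps$center_a != dps$center_b), 2L)

  # inverted block: anti-diagonal with opposite strands
  g3 <- quickGenome("g3", c(1000, 5000, 9000), clusters = c("a", "b", "c"),
                    strands = c("+", "+", "+"))
  g4 <- quickGenome("g4", c(1000, 5000, 9000), clusters = c("c", "b", "a"),
                    strands = c("-", "-", "-"))
  dp2 <- dotPlotData(g3, g4)
  dp2 <- dp2[order(dp2$center_a), ]
  expect_equal(order(dp2$center_b), rev(seq_len(nrow(dp2))))
  expect_false(any(dp2$same_strand))
})

test_that("alignment export tags gang members and links shared clusters", {
  fx <- reportFixture()
  out <- exportGangAlignment(fx$gs, list(fx$gang))
  expect_equal(sum(out$tracks$gang_id == "gang_01", na.rm = TRUE), 9L)
  expect_equal(unique(out$connectors$genome_a), c("g1", "g2"))
  expect_true(all(out$connectors$cluster_id %in% c("a", "b", "c")))

  d <- tempfile()
  writeGangTables(list(fx$gang), fx$gs, d)
  expect_true(all(file.exists(file.path(d, c("gangs.json", "gangs.tsv",
                                             "topology.tsv",
                                             "gang_members.gff3")))))
  jj <- jsonlite::read_json(file.path(d, "gangs.json"))
  expect_equal(jj[[1]]$gang_id, "gang_01")
})
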