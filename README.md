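# geneGangs

Detection of **gene gangs** — evolutionarily conserved groups of three or
more co-localized monocistronic genes — in sets of annotated genomes,
together with the single-copy core gene (SCCG) distance-conservation
analyses that justify the proximity threshold the method uses.

## The problem

Large dsDNA viruses such as the chloroviruses (~330 kbp, 300–420 genes)
keep their gene *content* well conserved while their gene *order* is
scrambled between lineages. Yet certain genes stay physically close to
one another in (nearly) every genome, regardless of order, strand, or
intervening genes. Such a group is a *gene gang*: a conserved structural
genomic element weaker than an operon (no shared promoter, no strand
constraint) but stronger than chance. Finding gangs requires (i) a
principled co-localization scale and (ii) an algorithm that turns
per-genome gene neighborhoods into disjoint cross-genome gangs.

## The method

**Distance scale.** For the set of single-copy core genes (clusters with
exactly one member in every genome), pairwise center-to-center distances
`d = |c_i − c_j|`, with `c = (start + end)/2`, are tested for
conservation two ways: *strictly constrained bins* (is the analogous pair
in other genomes within the seed pair's 1-kbp bin ± 250 bp?) and
*growing bins* (is the pair within `[0, b]` in both genomes, `b` growing
1 kbp at a time?). The growing-bin curve is compared against a
random-shuffle null — the empirical CDF of **all** pairwise gene
distances in a genome — and the half-maximal point of the
(observed − null) curve gives the largest distance at which conservation
is reliably non-random.

**Gang detection.** With parameters `maxGenomicDistance = 3500` bp,
`minGenomePrevalence = 34` (of 41), `paralogCorrectionThreshold = 15`,
`largeClusterThreshold = 80`, `minGangClusters = 3`:

1. clusters with > 80 members are *large* (highly paralogous) and never
   seed gangs; all others are *seed clusters*;
2. each seed cluster's *genomic grouping* in a genome is the seed
   feature(s) plus every feature within 3500 bp center-to-center (either
   strand, either side); groupings across genomes form a *cluster gang*;
3. cluster gangs whose seed occurs in < 34 genomes are dropped, and
   members not consistently co-localized (present in the windows of
   < 34 genomes) are pruned;
4. cluster gangs sharing any cluster id are merged (connected
   components) until no feature belongs to two gangs;
5. a paralog-correction pass re-admits edge paralogs of gang clusters
   found near members in ≥ 15 genomes;
6. gangs keep ≥ 3 cluster ids and members from every genome.

The *ruliness* of a gang cluster is the fraction of genomes containing
it within the gang; a gang's ruliness is the minimum over its clusters
(1.00 = "ruly"). A ruliness filter produces strict or permissive views.

The package also reports per-gang topology (consensus member count,
synteny up to reversal, strand conservation, alien-gene infiltration),
exports dot-plot/alignment tables, and ships a synthetic genome
simulator with planted gangs for end-to-end validation.

## Worked example

```r
library(geneGangs)

sim <- simulateGenomeSet(SimConfig(nGenomes = 8, shuffleIntensity = 20),
                         seed = 42)
gs <- sim$genomes
gs
#> GenomeSet of 8 genomes | 2434 features, 378 homology clusters

identifySCCGs(gs)
#> SCCGSet: 155 single-copy core clusters over 8 genomes

gangs <- detectGeneGangs(gs, GangParams(minGenomePrevalence = 7))
gangs[[1]]
#> GeneGang gang_01 | 5 cluster ids, ruliness 1.000 | 40 features in 8 genomes

head(topologyTable(gangs, gs)[, 1:5])
#>   gang_id max_members consensus_members n_ruly_genomes n_syntenic_genomes
#> 1 gang_01           5                 5              8                  8
#> 2 gang_02          10                10              8                  8
#> ...

curve <- growingBinAnalysis(genomes(gs)[[1]], genomes(gs)[[2]],
                            identifySCCGs(gs), tree = sim$tree)
curve
#> GrowingBinCurve G01 vs G02 | half-max threshold 14000 bp
round(head(binTable(curve), 4), 3)
#>   bin_upper_bp n_pairs_a observed null_a null_b subtracted
#> 1         1000        51    0.863  0.003  0.003      0.860
#> 2         2000       100    0.820  0.007  0.007      0.813
#> 3         3000       127    0.764  0.010  0.010      0.754
#> 4         4000       163    0.736  0.014  0.014      0.722
```

The five detected gangs are exactly the five planted by the simulator
(sizes 3–10), each perfectly ruly; the growing-bin curve shows strong
distance conservation at small bins (0.86 observed vs 0.003 expected
under random shuffling) decaying to half its initial value by 14 kbp for
this moderately shuffled pair.

Real data enter through `readGenBank()` (GenBank flat files),
`readGFF3Genome()` (GFF3 + FASTA), `readClusterTable()` (per-feature
homology-cluster TSV) and `readNewick()`. A command-line front end with
`simulate` / `detect` / `sccg-distance` / `report` subcommands lives at
`inst/scripts/genegangs.R`.

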