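---
title: "Detecting conserved gene neighborhoods: methods and design notes"
author: "geneGangs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved gene neighborhoods: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneGangs)
```

## The model

A *gene gang* is a set of three or more monocistronic genes that remain
physically co-localized across (nearly) all genomes of a set, with no
constraint on gene order, strand, or intervening genes. The package
operationalizes "co-localized" as a center-to-center distance
`|c_i - c_j| <= maxGenomicDistance`, where `c = (start + end)/2` in
1-based inclusive coordinates. Centers may be half-integral and are kept
exact; they are invariant under strand flips, which is what makes the
distance a strand-free notion of proximity. Genomes are treated as
linear, and distances across contig breaks are undefined (effectively
infinite): proximity on a fragmented assembly cannot be asserted across
a break.

The co-localization scale is not arbitrary: the single-copy core gene
(SCCG) analyses measure, over the clusters present exactly once in every
genome, how far pairwise distances stay conserved. The strictly
constrained bin analysis asks whether the *specific* distance of a pair
recurs (within its 1-kbp bin widened by a 250-bp buffer) in other
genomes; the growing bin analysis asks whether pairs stay within a
*maximum* distance `[0, b]` in both genomes of a comparison as `b`
grows. The growing-bin curve is referenced against a random-shuffle
null: the empirical CDF of all pairwise gene distances in a genome,
which is the expected conserved fraction if genes shuffled independently
while preserving the genome's internal distance distribution. The
half-maximal point of the (observed − null) curve marks the largest bin
size with reliably non-random conservation.

## The detection pipeline

1. **Cluster classification.** A homology cluster with strictly more
   than `largeClusterThreshold` (default 80) members across the whole
   set is *large*; resolving the genomic context of that many paralogs
   is ambiguous, so large clusters never seed gangs. The boundary was
   chosen strict (`> 80`, so exactly 80 members is still a seed) and is
   a parameter, since the opposite convention is defensible.
2. **Groupings and cluster gangs.** Each seed cluster's grouping in a
   genome is the seed feature(s) plus every feature within the window
   (inclusive: a neighbor at exactly 3500 bp belongs, at 3501 bp does
   not). When annotation errors split a gene into several proximal seed
   features, each contributes its own window and the union is taken.
3. **Prevalence filter.** Cluster gangs whose seed occurs in fewer than
   `minGenomePrevalence` (default 34) genomes are dropped. Within each
   retained gang, member features whose cluster occurs in the gang's
   windows in fewer than `minGenomePrevalence` genomes are pruned
   (unclustered features can never qualify). This second half matters:
   a single chance juxtaposition in one genome would otherwise link two
   unrelated neighborhoods through the merge step, and transitively the
   whole genome — merging would converge to one all-encompassing gang.
   Pruning to *consistently* co-localized members is also what
   guarantees that every cluster id of a finished gang has ruliness of
   at least `minGenomePrevalence / nGenomes`.
4. **Merging.** Cluster gangs that share any cluster id among their
   member features are merged, repeatedly, until no feature belongs to
   two gangs. The fixpoint of that iteration equals the connected
   components of the cluster-id overlap graph, which is what is
   computed in one pass (union-find). Equality with an independently
   coded components computation is property-tested, not assumed.
5. **Paralog correction.** Because large clusters cannot seed, a
   paralog sitting at the edge of a neighborhood may be missed. One
   pass scans around every member feature for non-members whose cluster
   is already a gang cluster id; if found in at least
   `paralogCorrectionThreshold` genomes they are admitted. The default
   is 15; 14 is an equally citable convention, so both are reachable
   through `GangParams`. The pass runs once and never moves a feature
   out of another gang (collisions are flagged instead), keeping gangs
   disjoint. Iterating the pass could in principle cascade admissions;
   a single pass is the conservative reading and keeps the result
   order-independent.
6. **Final filter and ruliness.** Gangs keep at least
   `minGangClusters` (default 3) cluster ids and at least one member in
   every genome. Ruliness of a cluster id is the fraction of genomes
   containing it within the gang; a gang's ruliness is the minimum over
   its ids. `rulinessFilter()` at 1.00 yields the strict view; no
   filter yields the permissive ("unruly") view. Filtering below the
   cluster minimum flags the gang degenerate rather than silently
   deleting it.

Gang ids are assigned by the gangs' minimal coordinate in the first
genome (ties by cluster-id signature), so results are reproducible;
permuting genome input order changes at most the labels, never the
memberships.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `maxGenomicDistance` | bp | 3500 | inside the 0–15 kbp non-random conservation range measured by the SCCG analyses, small enough to avoid merge runaway |
| `minGenomePrevalence` | genomes | 34 (of 41) | ~83% prevalence floor for seeds and members; also the ruliness floor of finished gangs |
| `paralogCorrectionThreshold` | genomes | 15 | edge paralogs must recur in over a third of genomes |
| `largeClusterThreshold` | members | 80 (strict >) | excludes highly paralogous families from seeding |
| `minGangClusters` | clusters | 3 | a "group" of two is a pair, not a gang |
| bin width / buffer / cap | bp | 1000 / 250 / 280000 | resolution, tolerance and range of the distance analyses |

## The synthetic generator

`simulateGenomeSet()` emulates the corpus the method targets: ~41
genomes, 319–416 ancestral gene slots, 155 core clusters present
single-copy in every genome, planted gangs of 3–10 members on
consecutive slots, two large paralog families, and accessory genes
filling the rest. Each genome derives from a single ancestor by
accessory presence/absence, optional gang-member deletion, and
Poisson-many block inversions and translocations (blocks of 2–25 genes)
that never split a planted gang. An inversion reverses genes and
internal gaps and flips strands, keeping the right-boundary gap at the
boundary; a translocation moves a block to a random insertion point.
Those are exactly the two operators needed to produce the observed
variation in gang topology (inversion, relocation, strand switching).
The ancestor-then-mutate design gives the set a real (star) phylogeny,
emitted as Newick with branch lengths proportional to the number of
events, so patristic distances have signal.

Design choices worth recording:

* **Deletions leave footprints.** A deleted gene becomes intergenic
  spacer, so pairwise distances among surviving genes are unchanged
  (pseudogenization rather than contraction). This keeps distance
  conservation an intrinsic property of the rearrangement process
  rather than of gene turnover.
* **Gene lengths are uniform 300–1500 bp with 50–90 bp gaps.** Mean
  gene-plus-gap near 1 kbp matches the gene density of the viral
  genomes being emulated; substantially longer genes cannot be packed
  at 300–420 genes per ~330 kbp genome.
* **Accessory clusters have bounded prevalence** (uniform 45–80% of
  genomes). Accessory genes are by definition below the core bar, so
  their prevalence is drawn strictly below the conservation threshold
  instead of fluctuating around it; a Bernoulli-loss model would let a
  few accessory clusters cross the gang-prevalence floor by chance and
  blur planted truth.
* **Non-planted conserved genes are spaced apart.** Core clusters not
  in gangs are laid out as isolated singletons or pairs separated from
  any other conserved gene by more than the collinearity window (and
  planted gangs by twice the window, `gangSpacingBp`). Planted truth is
  then the only persistent ≥3-cluster neighborhood, which is what makes
  exact recovery a meaningful test. Real genomes are *not* like this —
  conserved genes cluster, which is precisely the discovery the method
  makes on real data — so passing recovery tests shows the pipeline
  recovers known structure, not that real corpora contain five gangs.
  A side effect of the spacing is that simulated genomes run some
  10–30% longer than the nominal 330 kbp.

What the generator does not emulate: sequence content (FASTA output is
placeholder `N` runs), indel-scale evolution, horizontal transfer,
multi-contig assemblies (simulated genomes are single-contig; the
analyses nevertheless handle multi-contig input, treating cross-contig
distances as infinite), and non-star phylogenies.

## Numerical and statistical choices

* Empty bins are reported `NA`, never 0 — a bin with no seed pairs
  carries no evidence.
* The constrained-bin conservation test widens the seed pair's 1-kbp
  bin by the buffer on each side (`[bin_low - 250, bin_high + 250]`);
  the alternative reading ("original distance ± 1250 bp") is not
  bin-centric and is not used. The buffer is a parameter.
* Every genome serves as seed genome and seed pairs are pooled;
  pooling is symmetric and reproducible.
* In the growing-bin analysis the denominator is the pair count of the
  *first* genome of the ordered pair; both orders can be computed. The
  subtracted curve uses the *second* genome's null.
* The observed growing-bin fraction is not forced monotone: a pair
  entering the denominator but not the numerator can dip the ratio
  transiently. The null CDFs are monotone by construction.
* The null CDF is computed over all genes, not only SCCGs, matching
  the model of all genes shuffling independently.
* The half-max threshold is the smallest bin upper edge at which the
  subtracted curve first reaches half its value at the first occupied
  bin; a curve that never gets there returns the cap flagged.
* Consensus gang order counts an order and its reversal as one
  arrangement (ties broken lexicographically); synteny of a genome
  missing some clusters is judged against the consensus restricted to
  the clusters it carries, so gene loss alone does not break synteny.
  Strand conservation is evaluated among syntenic genomes after
  normalizing reversed genomes (a genome-wide reversal flips both
  order and strands), against the modal pattern or its global
  inversion.
* An *alien* is any feature between the outermost gang members of a
  genome lacking a gang cluster id, unclustered features included.

One validation deserves a statistical note. Checking that heavily
shuffled genomes track the random-shuffle null "within binomial
standard error at every bin" is only sound if the tallied events are
independent, and the full set of SCCG pairs is not: all pairs share
genes, which inflates the sampling noise several-fold over the binomial
value, and a 280-bin family pushes the expected maximum z-score to
about `sqrt(2 log 280) ≈ 3.4` even under a true null. The test suite
therefore pools, over 200 label-shuffles of a heavily shuffled genome
(gene positions fixed, labels permuted), one *disjoint* random pairing
of the SCCGs per shuffle. Disjoint pairs share no genes, the pooled
trials are independent, and the binomial 3-SE band at every bin is then
the right yardstick. The shuffled genome uses a homogeneous layout (no
planted gangs, no inter-block spacing), because the spacing device
described above makes core genes positionally non-exchangeable with the
gene population at large, which would bias the SCCG-pair distance
distribution relative to the all-gene null for reasons unrelated to the
null model itself.

## Problem sizes used by the tests

Unit tests run on hand-built genomes of 2–20 genes, where every
expected value is computed by an independent brute-force enumeration
frozen into the test. End-to-end checks use the default corpus scale
(41 genomes, ~370 gene slots, five planted gangs, shuffle intensity 20)
across ten simulation seeds for exact planted recovery, and smaller
sets (6–12 genomes, 80–130 genes) for invariants such as feature
disjointness, order invariance, determinism and file round-trips. The
merge step is cross-checked against an independent graph-components
oracle on 200 random instances.

## Known limitations

* The pipeline inherits the method's sensitivity to its two main
  parameters; on gene-dense genomes with high collinearity a too-large
  window or too-low prevalence floor merges everything. The
  all-encompassing outcome triggers a warning, not an error.
* Paralog correction is a single pass; pathological cases where an
  admitted paralog would license further admissions stay unadmitted.
* Synteny and strandedness judgments on gangs whose arrangement is
  genuinely type-specific (different fixed arrangements in different
  clades) report the majority arrangement only; per-genome
  classifications are exported so downstream analyses can see the
  type structure.
* `readGenBank()` is a deliberately minimal flat-file CDS reader
  (locus_tag/protein_id/product, join() collapsed to the outer span);
  it is not a general GenBank parser.
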