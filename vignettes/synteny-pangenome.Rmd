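---
title: "Synteny-constrained orthology and pan-genome annotation with synpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-constrained orthology and pan-genome annotation with synpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synpan)
```

## The problem

Protein-similarity searches alone cannot resolve orthology in genomes with
a history of duplication. A gene family with tandem copies, or a lineage
that went through a whole-genome duplication (WGD), produces many
high-scoring hits per gene, and graph-based orthogrouping lumps all of
them together. The central observation this package builds on is that,
within a *syntenic region* — a stretch of conserved gene order between two
chromosomes that share ancestry — homologs are expected to be exactly
single copy per genome (per ploidy level). Constraining similarity hits to
orthogroup membership *and* collinear gene order therefore turns noisy hit
tables into a near 1:1 (or 1:ploidy) orthology map, which in turn can be
decoded into a reference-anchored pan-genome annotation that exposes gene
presence–absence (PAV) and copy-number variation (CNV) across genomes.

`synpan` implements that whole chain: gene-annotation normalization,
tandem-array collapsing, orthogroup-constrained collinear chaining into
blocks and regions, optional secondary scans for WGD-derived paralogous
regions, within-region orthogroup refinement, and pan-genome construction
— plus a seeded genome-evolution simulator that generates every dataset
the test suite and the acceptance script use.

## Rank space, not bp space

All synteny inference runs on *gene rank order*, not physical
coordinates: the i-th gene on a chromosome sits at position i. After
tandem arrays are collapsed, inference moves to the condensed rank among
array representatives (`array_ord`). Working in rank space makes the
tunables (block size, gaps, buffer radius) independent of gene density
and genome size. Physical bp coordinates are carried along and reported
for blocks and pan-genome entries, but never drive inference.

## The pipeline, stage by stage

**Annotation intake.** GFF3 (parsed with `rtracklayer`) or BED input is
normalized to one row per gene, sorted by `(chrom, start)`; rank ties on
`start` break by `end`, then gene id, so output is reproducible for any
input order. Coordinates are 0-based half-open internally; GFF3 I/O
converts at the boundary. Chromosomes with fewer than `blkSize` genes
cannot host a block and are dropped up front.

**Tandem arrays.** Within each (genome, chromosome, orthogroup) holding
more than one gene, members are clustered in one dimension: the sorted
rank list is split wherever the adjacent gap exceeds `synBuff`. This
gap-splitting is exactly density-based clustering (DBSCAN) in one
dimension with reachability distance `synBuff` and minPts 1, and it is
trivially oracle-checkable, which is why it is implemented directly. The
representative is the member closest to the array's median rank; ties
break by longest peptide when peptide lengths are supplied, then by the
lexicographically smallest gene id. Collapsing arrays to representatives
masks tandem copy-number noise from the collinearity model; the members
come back in the final pan-genome with an `arrayMember` flag.

**Hit decoration.** Reciprocal hit files are merged so each unique
(query, target) pair appears once, keeping the maximum bitscore (the
strongest evidence wins; the genome with more gene models is the query).
Each hit is annotated with positions, array flags, a shared-orthogroup
flag, and the score rank `scrRank` — the dense rank of bitscore among all
hits sharing a gene, so rank 1 marks a gene's single best hit and equal
scores share a rank. Score ranks are recomputed on the unmasked subset in
every scan, because masked scans (polyploid self-synteny, secondary hits)
must rank the *remaining* candidates.

**Potential anchors.** A hit can anchor a block when both genes are array
representatives, it survives any mask, `scrRank` is within the top-n
cutoffs on both sides (`nHits` defaults to the partner genome's ploidy —
the single-copy expectation generalized to polyploids), and, by default,
both genes share an orthogroup. Condensed x/y rank positions are then
recomputed per chromosome pair over the flagged subset; chaining operates
on those.

**Collinear chaining.** The collinearity engine is a deterministic
dynamic program over the spec of MCScanX-style block finding: a chain is
strictly increasing in x with y strictly monotone (orientation `+`/`-`),
consecutive members may skip at most `nGaps` ranks per axis, chains score
by hit count, and maximal chains are extracted greedily (ties: smaller
minimum x, then smaller minimum y, then `+`). Chains shorter than
`blkSize` are discarded. The greedy-DP is validated against exhaustive
enumeration on hundreds of small random instances in the test suite.
Scoring by hit count — rather than a significance-weighted score — is a
deliberate simplification; its one observable cost is discussed under
*Limitations*.

**Block refinement.** Initial chains are cleaned up in the cascade:
potential anchors within a Chebyshev radius `synBuff` (in array-rank
space) of any initial anchor are re-chained; cleaned anchors are
clustered into regions by DBSCAN (Euclidean, eps `synBuff`, minPts
`blkSize`; clusters below `blkSize` drop); chaining reruns within each
region to give the final anchors; a fine DBSCAN (eps `blkSize`) on
re-ranked anchor positions splits a chain into sub-blocks only when every
piece keeps at least `blkSize` anchors; and where two non-duplicated
blocks overlap on both axes, the overlap anchors go to the block holding
the longest consecutive run there. All chaining inside the cascade uses
the pair-level condensed ranks computed once per chromosome pair —
re-condensing sparse subsets would let chains bridge arbitrarily large
real gaps. The DBSCAN implementation processes points in sorted (x, y)
order and assigns border points to the first core cluster that reaches
them, so clustering is order-independent and byte-reproducible.

**Regions, buffer, coordinates.** Final anchors are re-clustered (eps
`synBuff`, minPts 1) into regions; every hit within Chebyshev `synBuff`
of an anchor is flagged `inBuffer` and inherits the nearest anchor's
region (ties to the lower region id). Chebyshev distance is used for
"radius in rank units on both axes" tests, Euclidean inside DBSCAN (the
conventional metric); the choice matters little at these radii but is
fixed for determinism. Block and region bp coordinates are the extrema of
their bounding anchor genes.

**Self-synteny and polyploid masking.** A haploid genome's self-synteny
is the identity: one block per chromosome, anchored by the array
representatives, with the chromosome id as block id. For ploidy p > 1 the
identity diagonal plus a `selfMaskRadius` (default 500 gene ranks)
neighborhood is masked — large tandem arrays would otherwise masquerade
as homeologous blocks — and the standard cascade reruns with
nHits = p − 1 to recover homeolog blocks.

**Secondary (paralog) scans.** With `nSecondaryHits > 0`, every hit
within `synBuff` of a primary anchor is masked and the cascade reruns
with the `*Second` parameter set, no orthogroup requirement, and
nHits = `nSecondaryHits`. On a pair of genomes sharing a pre-speciation
WGD analyzed as haploids, the primary scan locks onto the orthologous
(same-subgenome) block set because paralog bitscores are lower, and the
secondary scan then recovers the crossed homeolog-to-ortholog block set.

**Orthogroup refinement in blocks.** When any genome has ploidy > 1 (or
on request), orthogroups are re-estimated inside syntenic regions as the
connected components of the reciprocal-best-hit graph restricted to
in-buffer hits, and the scan reruns once with the combined labels. This
is a behavioral substitute for rerunning a full orthogrouping tool per
region — same intent (separating homeolog columns that a global
orthogroup lumps), much lighter machinery. Between purely haploid genomes
it is off by default; it adds little there.

**Pan-genome construction.** Syntenic orthogroups are the connected
components of the graph whose edges are in-buffer, orthogroup-consistent
hits across all genome pairs (tandem members inherit their
representative's component; isolated genes form singletons so the
components partition the gene universe). Every array representative in
every genome then receives a reference rank position: reference genes at
their own rank, others by interpolation along 1:1 ungapped anchor runs —
runs of anchors stepping by exactly one rank on both axes with a fixed
sign; any larger jump splits the run. Inside a run, positions
interpolate linearly; just outside, they extrapolate at unit slope from
the nearest run end (within `synBuff`). Each orthogroup's positions are
split by reference chromosome and at gaps > `synBuff`; clusters holding
at least `propAssignThresh` of the positioned members survive (if none
does, the largest cluster is kept — the alternative would silently drop
whole orthogroups), at most `maxPlacementsPerRefChr` per chromosome
(ranked by member proportion, then size, then position). An entry is
placed at the median position of its cluster, mapped to bp via the
nearest backbone gene; the median is used because it is insensitive to a
single mis-interpolated member. Members the strict placement skipped are
folded back in with flags: `indirectSyn`, `arrayMember`, `NSOrtho` (from
an optional global ortholog map), and `absent` marks empty (entry,
genome) cells. PAV/CNV matrices derive directly from member counts.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `blkSize` | 5 | hits | minimum collinear hits per block; also DBSCAN minPts |
| `nGaps` | 5 | ranks | max skipped ranks between chain neighbors, per axis |
| `synBuff` | 100 | ranks | anchor buffer radius; tandem gap; region DBSCAN eps |
| `nHits1/2` | ploidy | hits | score-rank cutoffs for anchor candidacy |
| `onlyOgAnchors` | TRUE | — | anchors must share an orthogroup |
| `nSecondaryHits` | 0 | hits | paralogous copies sought after masking primary synteny |
| `blkSize/nGaps/synBuffSecond` | = primary | — | parameter set of the secondary scan |
| `selfMaskRadius` | 500 | ranks | diagonal mask for polyploid self scans |
| `propAssignThresh` | 0.5 | fraction | min member share for a pan-genome placement |
| `maxPlacementsPerRefChr` | 2 | entries | placements of one orthogroup per ref chromosome |

The defaults are intended to be robust across very different divergence
scales; raising `blkSize`/`nGaps` coarsens blocks (useful when recent WGD
duplicates every block), widening `synBuff` merges regions across larger
rearrangements.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_genomes()` generate: a shared ancestral gene
order; per-branch inversions, translocations, tandem duplications and
gene losses; an optional whole-genome duplication (chromosomes duplicated
with a subgenome label); and bitscore-realistic hits — ortholog scores
drawn from Normal(500, 30), pairs related only through a pre-split WGD
decayed by a factor (default 0.7, giving ~5 sigma of separation between
ortholog and homeolog scores), plus ~1% spurious low-score hits. Defaults
follow the validation conditions used throughout: 3 genomes, 2
chromosomes of 500 genes; per branch 2 inversions of 20–50 genes, 1
translocation of 20 genes, 2% gene loss, 1% tandem duplication. One
seeded RNG stream drives everything, so a scenario plus seed reproduces
byte-identical fixtures, and the event-log JSON replays to the identical
dataset.

The simulator does **not** model: sequence evolution (hits are drawn, not
aligned), annotation error (fragmented or merged gene models), missing or
unplaced scaffolds, segmental (sub-chromosomal) duplications, gene
conversion between homeologs, or biased fractionation after WGD. Passing
tests therefore demonstrate that the *algorithms* recover planted
structure under realistic noise; they do not certify performance on real
annotations, whose failure modes are dominated by annotation quality.

## Numerical and degenerate-input choices

* Rank ties (`start`, then `end`, then id) and every clustering pass are
  deterministic; two runs on one fixture produce byte-identical outputs,
  which the test suite asserts file by file.
* Equal bitscores share a dense `scrRank`, so ties never silently drop a
  candidate; duplicate (query, target) rows keep max bitscore, then max
  pident, then first occurrence.
* Empty inputs: no arrays, no anchors, or no blocks are valid outcomes
  and return empty tables; an empty hit file, a duplicated gene id, a
  gene in two orthogroups, or a genome losing all chromosomes at QC are
  fatal.
* Interpolation targets out of every anchor run's reach get NA positions
  and the containing orthogroups are appended with NA coordinates rather
  than being dropped.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the full pipeline on
simulated trios of ~1,000 genes per genome (2 chromosomes x 500 genes)
and WGD pairs of ~2,000 genes, 100-instance tandem-array sweeps,
200-instance chaining-oracle sweeps, and a 10% reference-withholding
interpolation experiment. These sizes keep a complete validation run in
the low minutes on one core while leaving every rate estimate with
denominators in the hundreds to thousands.

## Known limitations

* **Minimum-evidence blocks under the null.** Scoring chains purely by
  hit count means a fully random gene-order permutation still yields
  blocks of exactly `blkSize` hits at a measurable rate (~0.5% of hits
  become anchors at the default scales; the acceptance script reports the
  honest value as `shuffled_anchor_rate_pct`). Significance-weighted
  chain scoring would suppress these but is deliberately out of scope;
  on real (non-random) inputs these marginal blocks are dwarfed by true
  synteny.
* The in-block orthogroup refinement is an RBH-component substitute, not
  a clone of a full orthogrouping tool; it separates WGD paralog columns
  well in simulation but does not build gene trees.
* Block overlap resolution ("longest run wins") is one reading of
  run-length decoding; alternatives would differ only at block edges.
* The riparian layout's vertical genome order is user input; no
  translocation-minimizing search is attempted.

## A worked run

```{r example, eval = FALSE}
library(synpan)

sim <- simulate_genomes(sim_scenario(seed = 7))
scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
print(scan)

pg <- build_pangenome(scan, ref = "genA")
print(pg)
summary(pg)

# plots: dotplot of one pair, riparian braid across all genomes
plot(scan, pair = names(scan$pairs)[1])
plot(riparian_layout(scan, genome_order = names(sim$genomes),
                     highlight = "chr1"))
```
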