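# synpan

Synteny-constrained orthology and reference-anchored pan-genome
annotation for sets of annotated genomes of arbitrary ploidy.

## The problem

Similarity searches between annotated genomes return many hits per gene
— tandem copies, whole-genome-duplication (WGD) paralogs, and spurious
matches — and graph-based orthogrouping lumps them together. `synpan`
resolves orthology by exploiting conserved gene order: within a syntenic
region, homologs are expected to be exactly single copy per genome (per
ploidy level). The pipeline collapses tandem arrays to representative
genes, restricts hits to orthogroup-consistent candidates, chains them
into collinear blocks, and decodes the resulting pairwise syntenic
orthologs into a pan-genome annotation on a chosen reference genome's
coordinate system, exposing gene presence–absence (PAV) and copy-number
variation (CNV).

## The model in brief

All inference runs in gene **rank space**. With hits placed at condensed
rank positions (x on the query genome, y on the target), a syntenic
**block** is a chain of hits strictly increasing in x, strictly monotone
in y (orientation `+`/`-`), with at most `nGaps` skipped ranks between
consecutive members on each axis, and at least `blkSize` members. Chains
score by hit count and are extracted greedily by a deterministic dynamic
program (the package's replacement for MCScanX-style block finding).
Anchor candidacy requires both genes to be tandem-array representatives
with score rank at most the partner genome's ploidy (`scrRank <= nHits`)
and, by default, shared orthogroup membership. Blocks are refined with
density-based clustering (DBSCAN, eps `synBuff`, minPts `blkSize`) into
**regions**; every hit within a Chebyshev radius `synBuff` of an anchor
is syntenic (`inBuffer`). Defaults: `blkSize = 5`, `nGaps = 5`,
`synBuff = 100`. Polyploid self scans mask the identity diagonal
(radius 500) and rerun with `nHits = ploidy - 1`; setting
`nSecondaryHits > 0` masks primary synteny and rescans without the
orthogroup constraint to recover WGD-derived paralogous regions.

For the pan-genome, every array representative receives a reference
rank: reference genes at their own rank, others by linear interpolation
along ungapped 1:1 anchor runs. Each syntenic orthogroup (connected
component of in-buffer, orthogroup-consistent hits across all pairs) is
placed at the median position of its positional cluster(s), subject to
`propAssignThresh` (0.5) and `maxPlacementsPerRefChr` (2); tandem
members, indirect members and optional non-syntenic orthologs are folded
in with flags.

A seeded genome-evolution simulator (ancestral gene order; per-branch
inversions, translocations, tandem duplications, losses; optional WGD;
bitscore-realistic noisy hits) provides ground truth for every test.

## Worked example

```r
library(synpan)

sim  <- simulate_genomes(sim_scenario(seed = 7))   # 3 genomes, 2 x 500 genes
scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
print(scan)
#> Synteny scan: 3 genomes, 3 genome pairs
#>   primary blocks: 36
#>   genA vs genB: 12 blocks, 959 anchors, 974 in-buffer hits
#>   genA vs genC: 12 blocks, 956 anchors, 969 in-buffer hits
#>   genB vs genC: 12 blocks, 953 anchors, 965 in-buffer hits

pg <- build_pangenome(scan, ref = "genA")
print(pg)
#> Pan-genome annotation on reference 'genA'
#>   entries: 1000  genomes: 3
#>   core entries (present in all genomes): 947 (94.7%)
summary(pg)
#> Pan-genome: 1000 entries across 3 genomes
#>   core: 947  dispensable: 53
#>   genes per genome:
#> genA genB genC
#>  995  992  988
```

Each simulated genome descends from a 1,000-gene ancestor through two
inversions, a translocation, 2% gene loss and 1% tandem duplication, so
~12 blocks per pair (rearrangement breakpoints split the 4 chromosome
pairs) and ~95% core entries are the expected outcome; the 1,000 entries
match the 1,000 ancestral genes exactly, and the per-genome totals equal
each genome's surviving gene count. `write_scan()` / `write_pangenome()`
emit the block, hit, PAV/CNV and pan-genome tables as deterministic TSV;
`plot(scan)` draws a block-colored dotplot and
`plot(riparian_layout(scan, ...))` a braided macro-synteny ribbon.

Real data enter through `read_annotation()` (GFF3/BED), `read_hits()`
(BLAST/DIAMOND outfmt 6, reciprocal files merged) and
`read_orthogroups()` (Orthogroups.tsv dialect); if no orthogroup file is
given, orthogroups are derived internally from reciprocal best hits.

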