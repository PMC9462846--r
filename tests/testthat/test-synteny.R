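# annotated two-genome toy pair: 12 single-copy orthologous genes on chr1
toy_pair <- function(n = 12L, bs = 300) {
  gA <- toy_genes(rep("chr1", n), seq_len(n) * 100L, genome = "gA")
  gB <- toy_genes(rep("chr1", n), seq_len(n) * 100L, genome = "gB")
  og <- stats::setNames(rep(sprintf("OG%03d", seq_len(n)), 2L),
                        c(gA$gene_id, gB$gene_id))
  gA <- assign_orthogroups(gA, og)
  gB <- assign_orthogroups(gB, og)
  gA <- find_tandem_arrays(gA, synteny_params())$genes
  gB <- find_tandem_arrays(gB, synteny_params())$genes
  h <- toy_hits(gA$gene_id, gB$gene_id, rep(bs, n), "gA", "gB")
  list(gA = gA, gB = gB, hits = h)
}

test_that("score ranks are dense per gene and orthogroup flags literal", {
  gA <- toy_genes(rep("chr1", 2L), c(100L, 200L), genome = "gA")
  gB <- toy_genes(rep("chr1", 4L), 1:4 * 100L, genome = "gB")
  og <- stats::setNames(c("OG0", "OG1", "OG0", "OG9", "OG1", "OG2"),
                        c(gA$gene_id, gB$gene_id))
  gA <- find_tandem_arrays(assign_orthogroups(gA, og), synteny_params())$genes
  gB <- find_tandem_arrays(assign_orthogroups(gB, og), synteny_params())$genes
  h <- toy_hits(rep(gA$gene_id[1L], 4L), gB$gene_id,
                c(300, 250, 250, 100), "gA", "gB")
  ah <- annotate_hits(h, gA, gB)
  expect_equal(sort(ah$scrRankQ), c(1L, 2L, 2L, 3L))  # dense rank
  expect_equal(ah$scrRankQ[order(-ah$bitscore)], c(1L, 2L, 2L, 3L))
  expect_equal(ah$scrRankT, rep(1L, 4L))              # single hit per target
  expect_equal(ah$isOg[match(gB$gene_id, ah$target)],
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("potential anchors honor nHits resolution by ploidy", {
  tp <- toy_pair()
  ah <- annotate_hits(tp$hits, tp$gA, tp$gB)
  # haploid x haploid: auto -> 1/1
  nh <- synpan:::resolve_nhits(synteny_params(), "gA", "gB")
  expect_equal(unname(nh), c(1L, 1L))
  # haploid query x tetraploid target: nHits1 = 4
  nh2 <- synpan:::resolve_nhits(synteny_params(ploidy = c(gB = 4L)),
                                "gA", "gB")
  expect_equal(unname(nh2), c(4L, 1L))
  # scrRank above the cutoff excludes the hit
  h2 <- data.table::copy(tp$hits)
  extra <- toy_hits(tp$gA$gene_id[1L], tp$gB$gene_id[5L], 100, "gA", "gB")
  h2 <- data.table::rbindlist(list(h2, extra))
  data.table::setattr(h2, "genomeQ", "gA")
  data.table::setattr(h2, "genomeT", "gB")
  ah2 <- annotate_hits(h2, tp$gA, tp$gB)
  fp <- flag_potential_anchors(ah2, 1L, 1L, onlyOg = FALSE)
  weak <- fp$query == tp$gA$gene_id[1L] & fp$target == tp$gB$gene_id[5L]
  expect_false(any(fp$isPotential[weak]))
  expect_equal(fp$scrRankQ[weak], 2L)
})

test_that("a colinear pair yields one full block and buffered hits", {
  tp <- toy_pair()
  ah <- annotate_hits(tp$hits, tp$gA, tp$gB)
  res <- synteny_pair(ah, synteny_params(), "gA", "gB")
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "+")
  expect_equal(res$blocks$n_anchors, 12L)
  expect_true(all(res$hits$isAnchor))
  expect_true(all(res$hits$inBuffer))
  # block bp coordinates equal the bounding anchors computed by brute force
  expect_equal(res$blocks$startQ, min(tp$gA$start))
  expect_equal(res$blocks$endQ, max(tp$gA$end))
  expect_equal(res$blocks$minAoQ, 1L)
  expect_equal(res$blocks$maxAoQ, 12L)
})

test_that("anchors are a subset of potential hits and of all hits", {
  sim <- small_sim()
  scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  h <- scan$pairs[[1L]]$hits
  expect_true(all(h$isPotential[h$isAnchor]))
  expect_true(all(h$inBuffer[h$isAnchor]))
  expect_true(all(!is.na(h$blk_id[h$isAnchor])))
  expect_true(all(is.na(h$blk_id[!h$isAnchor])))
})

test_that("an inversion is recovered as a '-' block within one region", {
  n <- 60L
  gA <- toy_genes(rep("chr1", n), seq_len(n) * 100L, genome = "gA")
  ordB <- seq_len(n); ordB[21:40] <- rev(ordB[21:40])   # 20-gene inversion
  gB <- toy_genes(rep("chr1", n), ordB * 100L, genome = "gB")
  # orthogroups pair gene i of gA with gene i of gB (ids, not row order)
  og <- stats::setNames(rep(sprintf("OG%03d", seq_len(n)), 2L),
                        c(sprintf("gA_g%03d", seq_len(n)),
                          sprintf("gB_g%03d", seq_len(n))))
  gA <- find_tandem_arrays(assign_orthogroups(gA, og), synteny_params())$genes
  gB <- find_tandem_arrays(assign_orthogroups(gB, og), synteny_params())$genes
  h <- toy_hits(sprintf("gA_g%03d", seq_len(n)),
                sprintf("gB_g%03d", seq_len(n)), rep(300, n), "gA", "gB")
  res <- synteny_pair(annotate_hits(h, gA, gB), synteny_params(),
                      "gA", "gB")
  expect_setequal(unique(res$blocks$orientation), c("+", "-"))
  expect_equal(length(unique(res$blocks$reg_id)), 1L)   # one region
  neg <- res$hits[res$hits$orientation %in% "-" & res$hits$isAnchor]
  inv_ids <- gA$gene_id[gA$ord %in% 21:40]
  expect_gte(mean(inv_ids %in% neg$query), 0.8)
})

test_that("hits near anchors are in buffer, far hits are not", {
  tp <- toy_pair()
  gA2 <- toy_genes(rep("chr1", 200L), seq_len(200L) * 100L, genome = "gA")
  gB2 <- toy_genes(rep("chr1", 200L), seq_len(200L) * 100L, genome = "gB")
  og <- stats::setNames(rep(sprintf("OG%03d", 1:200), 2L),
                        c(gA2$gene_id, gB2$gene_id))
  gA2 <- find_tandem_arrays(assign_orthogroups(gA2, og),
                            synteny_params())$genes
  gB2 <- find_tandem_arrays(assign_orthogroups(gB2, og),
                            synteny_params())$genes
  # diagonal anchors on genes 1..40; one near off-diagonal hit, one far
  h <- toy_hits(gA2$gene_id[1:40], gB2$gene_id[1:40], rep(300, 40),
                "gA", "gB")
  near <- toy_hits(gA2$gene_id[43L], gB2$gene_id[40L], 120, "gA", "gB")
  far <- toy_hits(gA2$gene_id[190L], gB2$gene_id[40L], 120, "gA", "gB")
  hh <- data.table::rbindlist(list(h, near, far))
  data.table::setattr(hh, "genomeQ", "gA")
  data.table::setattr(hh, "genomeT", "gB")
  res <- synteny_pair(annotate_hits(hh, gA2, gB2), synteny_params(),
                      "gA", "gB")
  hn <- res$hits[res$hits$query == gA2$gene_id[43L]]
  hf <- res$hits[res$hits$query == gA2$gene_id[190L]]
  expect_true(hn$inBuffer)        # 3 ranks off the diagonal, synBuff = 100
  expect_equal(hn$reg_id, res$blocks$reg_id[1L])
  expect_false(hf$inBuffer)       # 150 ranks from every anchor
})

test_that("self-synteny: haploid identity blocks; polyploid homeologs", {
  p2 <- synteny_params(ploidy = c(gW = 2L), orthofinderInBlk = FALSE)
  # haploid: one self block per chromosome
  gH <- toy_genes(rep(c("chr1", "chr2"), each = 10L),
                  rep(1:10 * 100L, 2L), genome = "gH")
  gH <- find_tandem_arrays(gH, synteny_params())$genes
  sh <- self_synteny(gH, synteny_params())
  expect_equal(nrow(sh$blocks), 2L)
  expect_true(all(sh$blocks$is_self))
  expect_equal(sh$blocks$blk_id, c("chr1", "chr2"))
  # simulated autotetraploid: per chromosome pair one off-diagonal block set
  sc <- sim_scenario(genomes = "gW", n_chrom = 1L, genes_per_chrom = 120L,
                     inversions = 0L, translocations = 0L, tandem_rate = 0,
                     loss_rate = 0, wgd_before_split = TRUE, seed = 17L)
  sim <- simulate_genomes(sc)
  gW <- assign_orthogroups(sim$genomes$gW, sim$og_truth)
  gW <- find_tandem_arrays(gW, p2)$genes
  ah <- annotate_hits(sim$hits$gW__gW, gW, gW)
  sw <- self_synteny(gW, p2, ah)
  hom <- sw$blocks[!(sw$blocks$chromQ == sw$blocks$chromT)]
  expect_gte(nrow(hom), 1L)
  expect_true(all(hom$is_self))
  # all anchors of the masked scan sit off the identity diagonal
  anc <- sw$hits[sw$hits$isAnchor]
  same <- anc$chromQ == anc$chromT
  if (any(same))
    expect_true(all(abs(anc$arrayOrdQ[same] - anc$arrayOrdT[same]) > 500L))
})

test_that("pair scans are deterministic", {
  sim <- small_sim()
  s1 <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  s2 <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  expect_identical(as.data.frame(s1$pairs[[1L]]$blocks),
                   as.data.frame(s2$pairs[[1L]]$blocks))
  expect_identical(as.data.frame(s1$pairs[[1L]]$hits),
                   as.data.frame(s2$pairs[[1L]]$hits))
})
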