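test_that("gene rank order follows start with end/gene_id tie-breaks", {
  td <- withr::local_tempdir()
  bed <- file.path(td, "g.bed")
  writeLines(c("chr1\t100\t200\tg1\t0\t+",
               "chr1\t50\t150\tg2\t0\t+",
               "chr1\t200\t300\tg3\t0\t+"), bed)
  g <- read_annotation(bed, "gA")
  expect_equal(g$ord[match(c("g1", "g2", "g3"), g$gene_id)], c(2L, 1L, 3L))

  gff <- file.path(td, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t500\t600\t.\t+\t.\tID=gLong",
               "chr1\tsrc\tgene\t500\t550\t.\t+\t.\tID=gShort"), gff)
  g2 <- read_annotation(gff, "gB")
  expect_lt(g2$ord[g2$gene_id == "gShort"], g2$ord[g2$gene_id == "gLong"])

  # rank order is a bijection per chromosome
  sim <- small_sim()
  for (gt in sim$genomes)
    for (ch in unique(gt$chrom))
      expect_equal(sort(gt$ord[gt$chrom == ch]), seq_len(sum(gt$chrom == ch)))
})

test_that("simulator GFF3 round-trips through load -> write -> load", {
  td <- withr::local_tempdir()
  sim <- small_sim()
  f1 <- file.path(td, "a.gff3")
  write_annotation_gff3(sim$genomes$gA, f1)
  g1 <- read_annotation(f1, "gA")
  f2 <- file.path(td, "b.gff3")
  write_annotation_gff3(g1, f2)
  g2 <- read_annotation(f2, "gA")
  cols <- c("gene_id", "chrom", "start", "end", "strand", "ord")
  expect_equal(as.data.frame(g2[, cols, with = FALSE]),
               as.data.frame(g1[, cols, with = FALSE]))
  expect_equal(as.data.frame(g1[, cols, with = FALSE]),
               as.data.frame(sim$genomes$gA[order(chrom, start),
                                            cols, with = FALSE]))
})

test_that("annotation loading rejects degenerate input", {
  td <- withr::local_tempdir()
  bed <- file.path(td, "dup.bed")
  writeLines(c("chr1\t1\t10\tg1", "chr1\t20\t30\tg1"), bed)
  expect_error(read_annotation(bed, "gA"), "duplicate gene_id")
})

test_that("chromosome QC drops sub-blkSize chromosomes and is idempotent", {
  g <- toy_genes(chrom = c(rep("chr1", 4L), rep("chr2", 5L)),
                 start = c(1:4, 1:5) * 100L)
  p <- synteny_params(blkSize = 5L)
  q <- qc_chromosomes(g, p)
  expect_false("chr1" %in% q$chrom)          # 4 genes < blkSize: dropped
  expect_equal(sum(q$chrom == "chr2"), 5L)   # exactly blkSize: retained
  expect_length(attr(q, "dropped"), 4L)
  # per-chromosome ranks unaffected, and QC is idempotent
  expect_equal(q$ord[q$chrom == "chr2"], 1:5)
  q2 <- qc_chromosomes(q, p)
  expect_equal(q2, q, ignore_attr = TRUE)
  # all chromosomes dropped is fatal and names the genome
  g2 <- toy_genes(chrom = rep("chr1", 3L), start = 1:3 * 100L,
                  genome = "tiny")
  expect_error(qc_chromosomes(g2, p), "tiny")
})

test_that("hit loading merges reciprocal files keeping the max bitscore", {
  td <- withr::local_tempdir()
  gA <- toy_genes(rep("chr1", 6L), 1:6 * 100L, genome = "gA")
  gB <- toy_genes(rep("chr1", 5L), 1:5 * 100L, genome = "gB")
  row12 <- function(q, t, bs, pid = 90)
    sprintf("%s\t%s\t%.1f\t300\t0\t0\t1\t300\t1\t300\t1e-50\t%.1f",
            q, t, pid, bs)
  fAB <- file.path(td, "ab.tsv")
  fBA <- file.path(td, "ba.tsv")
  writeLines(row12("gA_g001", "gB_g001", 300), fAB)
  writeLines(row12("gB_g001", "gA_g001", 280), fBA)
  h <- read_hits(c(fAB, fBA), gA, gB)
  expect_equal(nrow(h), 1L)
  expect_equal(h$bitscore, 300)              # max-merge
  expect_equal(attr(h, "genomeQ"), "gA")     # more gene models = query
  # trivial self rows removed on intragenomic load
  fAA <- file.path(td, "aa.tsv")
  writeLines(c(row12("gA_g001", "gA_g001", 500),
               row12("gA_g001", "gA_g002", 210)), fAA)
  hs <- read_hits(fAA, gA, gA)
  expect_equal(nrow(hs), 1L)
  expect_false(any(hs$query == hs$target))
  # empty file is fatal
  fE <- file.path(td, "empty.tsv")
  writeLines(character(0), fE)
  expect_error(read_hits(fE, gA, gB), "empty")
  # reloading the merged output is idempotent
  fM <- file.path(td, "merged.tsv")
  writeLines(row12(h$query, h$target, h$bitscore, h$pident), fM)
  h2 <- read_hits(fM, gA, gB)
  expect_equal(as.data.frame(h2), as.data.frame(h))
})

test_that("orthogroup tables map genes uniquely and round-trip", {
  td <- withr::local_tempdir()
  f <- file.path(td, "og.tsv")
  writeLines(c("OG0\tg1,g2\th1", "OG1\tg3\th2"), f)
  og <- read_orthogroups(f)
  expect_equal(unname(og[c("g1", "g2", "h1")]), rep("OG0", 3L))
  expect_true(is.na(og["g9"]))
  f2 <- file.path(td, "dup.tsv")
  writeLines(c("OG0\tg1", "OG1\tg1"), f2)
  expect_error(read_orthogroups(f2), "more than one orthogroup")
  # simulator truth round-trips through the writer/reader pair
  sim <- small_sim()
  f3 <- file.path(td, "truth.tsv")
  write_orthogroups(sim$og_truth, sim$genomes, f3)
  back <- read_orthogroups(f3)
  expect_equal(back[names(sim$og_truth)], sim$og_truth)
})
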