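test_that("ancestor construction is dimensioned and deterministic", {
  sc <- sim_scenario(n_chrom = 2L, genes_per_chrom = 100L, seed = 1L)
  a1 <- simulate_ancestor(sc)
  expect_equal(nrow(a1), 200L)
  expect_equal(as.integer(table(a1$chrom)), c(100L, 100L))
  a2 <- simulate_ancestor(sc)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  # bp coordinates strictly increase with rank within a chromosome
  g <- synpan:::state_to_genes(a1, "anc")
  for (ch in unique(g$chrom))
    expect_true(all(diff(g$start[g$chrom == ch][order(g$ord[g$chrom == ch])])
                    > 0))
})

test_that("branch events edit the genome as declared", {
  sc <- sim_scenario(n_chrom = 2L, genes_per_chrom = 60L, seed = 2L)
  anc <- simulate_ancestor(sc)
  # single inversion: one contiguous segment reversed, all else identity
  set.seed(10)
  ev_inv <- list(inversions = 1L, inversion_size = c(20L, 20L),
                 translocations = 0L, tandem_rate = 0, loss_rate = 0,
                 wgd = FALSE)
  ch <- evolve_branch(anc, ev_inv, "kid")
  expect_equal(nrow(ch$state), nrow(anc))
  per_chrom <- split(ch$state$anc, ch$state$chrom)
  anc_per_chrom <- split(anc$anc, anc$chrom)
  n_diff <- 0L
  for (cc in names(per_chrom)) {
    d <- per_chrom[[cc]] != anc_per_chrom[[cc]]
    if (any(d)) {
      rng <- range(which(d))
      expect_equal(rng[2L] - rng[1L] + 1L, 20L)
      expect_equal(per_chrom[[cc]][rng[1L]:rng[2L]],
                   rev(anc_per_chrom[[cc]][rng[1L]:rng[2L]]))
      n_diff <- n_diff + 1L
    }
  }
  expect_equal(n_diff, 1L)
  # zero loss: the truth map is a bijection over parent genes
  expect_equal(sort(ch$map$parent_gene), sort(anc$gene_id))
  expect_false(any(is.na(ch$map$child_gene)))
  # whole-genome duplication doubles chromosomes and genes
  set.seed(11)
  ev_wgd <- list(inversions = 0L, inversion_size = c(1L, 1L),
                 translocations = 0L, tandem_rate = 0, loss_rate = 0,
                 wgd = TRUE)
  w <- evolve_branch(anc, ev_wgd, "dup")
  expect_equal(nrow(w$state), 2L * nrow(anc))
  expect_equal(length(unique(w$state$chrom)), 2L * 2L)
  rels <- table(w$map$relation)
  expect_equal(unname(rels["ortholog"]), nrow(anc))
  expect_equal(unname(rels["wgd_paralog"]), nrow(anc))
  # every parent gene has exactly one copy per subgenome
  expect_true(all(table(w$state$anc, w$state$sub) == 1L))
})

test_that("hit noise separates orthologs from WGD paralogs as configured", {
  sc <- sim_scenario(genomes = c("gA", "gB"), n_chrom = 1L,
                     genes_per_chrom = 250L, inversions = 0L,
                     translocations = 0L, tandem_rate = 0, loss_rate = 0,
                     wgd_before_split = TRUE, paralog_decay = 0.7,
                     spurious_rate = 0, seed = 19L)
  sim <- simulate_genomes(sc)
  h <- sim$hits$gA__gB
  sub_of <- stats::setNames(sim$truth$sub, sim$truth$gene_id)
  cross <- sub_of[h$query] != sub_of[h$target]
  ratio <- mean(h$bitscore[cross]) / mean(h$bitscore[!cross])
  expect_lt(abs(ratio - 0.7), 0.03)
  # no spurious hits, no loss, no WGD: hit count == shared pair count
  sc0 <- sim_scenario(genomes = c("gA", "gB"), n_chrom = 1L,
                      genes_per_chrom = 100L, inversions = 0L,
                      translocations = 0L, tandem_rate = 0, loss_rate = 0,
                      spurious_rate = 0, seed = 20L)
  sim0 <- simulate_genomes(sc0)
  expect_equal(nrow(sim0$hits$gA__gB), 100L)
})

test_that("fixtures round-trip through the readers and the event log", {
  td <- withr::local_tempdir()
  sc <- sim_scenario(genomes = c("gA", "gB"), n_chrom = 2L,
                     genes_per_chrom = 60L, inversions = 1L,
                     inversion_size = c(10L, 15L), translocations = 1L,
                     translocation_size = 5L, tandem_rate = 0.02,
                     loss_rate = 0.02, seed = 33L)
  sim <- simulate_genomes(sc)
  out <- file.path(td, "fx")
  write_fixture(sim, out)
  # refusing to clobber a non-empty directory
  expect_error(write_fixture(sim, out), "not empty")
  # annotations load back identically (both formats)
  for (g in names(sim$genomes)) {
    gg <- read_annotation(file.path(out, paste0(g, ".gff3")), g)
    gb <- read_annotation(file.path(out, paste0(g, ".bed")), g)
    cols <- c("gene_id", "chrom", "start", "end", "ord")
    expect_equal(as.data.frame(gg[, cols, with = FALSE]),
                 as.data.frame(sim$genomes[[g]][, cols, with = FALSE]))
    expect_equal(as.data.frame(gb[, cols, with = FALSE]),
                 as.data.frame(gg[, cols, with = FALSE]))
  }
  # truth orthogroups round-trip
  og <- read_orthogroups(file.path(out, "orthogroups.tsv"))
  expect_equal(og[names(sim$og_truth)], sim$og_truth)
  # hits load through read_hits
  h <- read_hits(file.path(out, "hits_gA__gB.tsv"),
                 sim$genomes$gA, sim$genomes$gB)
  expect_gt(nrow(h), 0L)
  # the event log replays to identical genomes and hits
  sim2 <- replay_fixture(file.path(out, "events.json"))
  for (g in names(sim$genomes))
    expect_identical(as.data.frame(sim2$genomes[[g]]),
                     as.data.frame(sim$genomes[[g]]))
  expect_identical(as.data.frame(sim2$hits$gA__gB),
                   as.data.frame(sim$hits$gA__gB))
  # total-gene conservation along each branch
  for (mp in sim$branch_maps) {
    kept <- sum(!is.na(mp$child_gene))
    expect_equal(kept, nrow(mp[mp$relation != "lost"]))
  }
})

test_that("the default demo scenario flows through the whole pipeline", {
  sim <- small_sim()
  expect_s3_class(sim, "genome_sim")
  scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  expect_gt(nrow(scan_blocks(scan, include_self = FALSE)), 0L)
  pg <- build_pangenome(scan, names(sim$genomes)[1L])
  expect_s3_class(pg, "pangenome")
})
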