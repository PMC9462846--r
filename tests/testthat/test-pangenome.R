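test_that("interpolation follows the linear formula and cluster rules", {
  # midpoint between ungapped anchors... anchors (10->10), (11->11), (12->12)
  a <- data.frame(t = c(10L, 11L, 12L), r = c(10, 11, 12),
                  ref_chrom = "chr1")
  ip <- interpolate_positions(a, targets = 11L)
  expect_equal(ip$ref_ord, 11.0)
  # inverted cluster: (5->20),(6->19),(7->18); t=6 -> 19.0
  ai <- data.frame(t = 5:7, r = c(20, 19, 18), ref_chrom = "chr1")
  expect_equal(interpolate_positions(ai, 6L)$ref_ord, 19.0)
  # a jump of 2 ref ranks between adjacent anchors splits the cluster:
  # the withheld position is then filled by unit-slope extrapolation
  aj <- data.frame(t = c(1:3, 4:6), r = c(1:3, c(6, 7, 8)),
                   ref_chrom = "chr1")
  ipj <- interpolate_positions(aj, c(2L, 5L))
  expect_equal(ipj$ref_ord[1L], 2.0)
  expect_equal(ipj$ref_ord[2L], 7.0)
  # between the two clusters: nearest-end extrapolation, not interpolation
  # across the split (t=3 -> r=3 is the nearest anchor end; t slightly past
  # it continues at unit slope)
  gap_probe <- interpolate_positions(
    data.frame(t = c(1:3, 10:12), r = c(1:3, 30:32), ref_chrom = "chr1"),
    4L)
  expect_equal(gap_probe$ref_ord, 4.0)
  # out of reach -> NA
  far <- interpolate_positions(a, 500L, synBuff = 100L)
  expect_true(is.na(far$ref_ord))
})

test_that("orthogroup placement respects propAssignThresh and the cap", {
  sogs <- data.table::data.table(
    gene_id = sprintf("g%d", 1:4), genome = c("gB", "gB", "gB", "gC"),
    sog_id = "sog1")
  pos <- data.table::data.table(
    gene_id = sprintf("g%d", 1:4),
    ref_chrom = c("chr1", "chr1", "chr1", "chr5"),
    ref_ord = c(100.0, 100.5, 101.0, 40.0))
  ent <- place_orthogroups(sogs, pos, synteny_params())
  # chr1 cluster holds 3/4 = 0.75 >= 0.5 -> kept; chr5 (0.25) dropped
  expect_equal(nrow(ent), 1L)
  expect_equal(ent$ref_chrom, "chr1")
  expect_equal(ent$ref_ord, 100.5)          # median of members
  # two balanced clusters on different chromosomes -> two entries
  pos2 <- data.table::copy(pos)
  pos2[4L, "ref_chrom" := "chr5"]
  sogs2 <- data.table::data.table(
    gene_id = sprintf("h%d", 1:4), genome = rep(c("gB", "gC"), 2L),
    sog_id = "sog2")
  pos2 <- data.table::data.table(
    gene_id = sprintf("h%d", 1:4),
    ref_chrom = c("chr1", "chr1", "chr5", "chr5"),
    ref_ord = c(10, 11, 200, 201))
  ent2 <- place_orthogroups(sogs2, pos2, synteny_params())
  expect_equal(nrow(ent2), 2L)
  expect_setequal(ent2$ref_chrom, c("chr1", "chr5"))
  # a single positioned member places directly
  ent3 <- place_orthogroups(
    data.table::data.table(gene_id = "z1", genome = "gB", sog_id = "sog3"),
    data.table::data.table(gene_id = "z1", ref_chrom = "chr2",
                           ref_ord = 7.0),
    synteny_params())
  expect_equal(ent3$ref_ord, 7.0)
  # the per-chromosome cap keeps the top clusters only
  sogs4 <- data.table::data.table(gene_id = sprintf("k%d", 1:7),
                                  genome = "gB", sog_id = "sog4")
  pos4 <- data.table::data.table(
    gene_id = sprintf("k%d", 1:7), ref_chrom = "chr1",
    ref_ord = c(1, 2, 3, 500, 501, 1000, 2000))
  ent4 <- place_orthogroups(sogs4, pos4,
                            synteny_params(propAssignThresh = 0.1,
                                           maxPlacementsPerRefChr = 2L))
  expect_equal(nrow(ent4), 2L)
  expect_equal(sort(ent4$ref_ord), c(2, 500.5))  # 3/7 and 2/7 clusters win
})

test_that("PAV and CNV matrices count members with CNV >= 1 <=> present", {
  long <- data.table::data.table(
    pgID = c("pg1", "pg1", "pg1", "pg1", "pg1", "pg2", "pg2", "pg2"),
    sog_id = "s", ref_chrom = "chr1", ref_ord = 1, ref_bp = 0L,
    genome = c("gA", "gC", "gC", "gC", "gB", "gA", "gB", "gC"),
    gene_id = c("a1", "c1", "c2", "c3", NA, "a2", "b2", "c4"),
    flag = c("synOg", "synOg", "arrayMember", "arrayMember", "absent",
             "synOg", "synOg", "synOg"))
  m <- pav_cnv_matrix(long)
  expect_equal(m$cnv["pg1", ], c(gA = 1L, gB = 0L, gC = 3L))
  expect_equal(m$pav["pg1", ], c(gA = TRUE, gB = FALSE, gC = TRUE))
  expect_equal(unname(m$cnv["pg2", ]), c(1L, 1L, 1L))
  expect_identical(m$pav, m$cnv >= 1L)
  # row sums equal per-genome gene counts assigned to entries
  expect_equal(colSums(m$cnv),
               c(gA = 2L, gB = 1L, gC = 4L))
})

test_that("pan-genome conserves every gene exactly once with sane flags", {
  sc <- sim_scenario(genomes = c("gA", "gB", "gC"), n_chrom = 2L,
                     genes_per_chrom = 150L, inversions = 1L,
                     inversion_size = c(10L, 20L), translocations = 0L,
                     tandem_rate = 0.02, loss_rate = 0.03, seed = 77L)
  sim <- simulate_genomes(sc)
  scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  pg <- build_pangenome(scan, "gA")
  real <- pg$long[pg$long$flag != "absent"]
  # conservation: every gene in exactly one entry
  expect_equal(sort(real$gene_id), sort(scan$genes$gene_id))
  expect_equal(anyDuplicated(real$gene_id), 0L)
  # tandem duplications surface as arrayMember rows next to a placed rep
  arr <- scan$genes[!is.na(scan$genes$array_id) & !scan$genes$is_array_rep]
  if (nrow(arr)) {
    am <- real[real$flag == "arrayMember"]
    expect_true(all(arr$gene_id %in% am$gene_id))
    rep_entry <- stats::setNames(real$pgID, real$gene_id)
    reps <- scan$genes[match(arr$array_id, scan$genes$array_id)]
    # members share the entry of their array's representative
    rep_ids <- scan$genes$gene_id[scan$genes$is_array_rep &
                                    !is.na(scan$genes$array_id)]
    names(rep_ids) <- scan$genes$array_id[scan$genes$is_array_rep &
                                            !is.na(scan$genes$array_id)]
    expect_equal(unname(rep_entry[arr$gene_id]),
                 unname(rep_entry[rep_ids[arr$array_id]]))
  }
  # simulated losses appear as absent cells in the PAV matrix
  tab <- table(sim$truth$anc, sim$truth$genome)
  lost_any <- sum(tab == 0L)
  expect_equal(sum(!pg$pav), lost_any)
  # wide table has one row per entry
  expect_equal(nrow(pg$wide), length(unique(pg$long$pgID)))
})

test_that("reference swap keeps the total gene coverage invariant", {
  sim <- small_sim()
  scan <- run_synteny(sim$genomes, sim$hits, og_map = sim$og_truth)
  pgA <- build_pangenome(scan, "gA")
  pgB <- build_pangenome(scan, "gB")
  nA <- nrow(pgA$long[pgA$long$flag != "absent"])
  nB <- nrow(pgB$long[pgB$long$flag != "absent"])
  expect_equal(nA, nB)   # both cover every gene exactly once
})
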