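#' Define a genome-evolution scenario
#'
#' A scenario fixes everything the simulator draws: the ancestral genome
#' size, the tree of genomes with per-branch rearrangement events, and the
#' similarity-score noise model. The same scenario and seed always produce
#' byte-identical fixtures.
#'
#' The default tree is a star: one ancestor giving rise to each named
#' genome, every branch carrying the stated inversions, translocation,
#' tandem duplications and gene losses. `wgd_before_split = TRUE` inserts a
#' whole-genome duplication on the stem branch, so every descendant carries
#' two homeologous copies of each ancestral chromosome — the configuration
#' used to exercise paralog masking and secondary-hit scans.
#'
#' @param genomes names of the leaf genomes to simulate.
#' @param n_chrom,genes_per_chrom ancestral genome dimensions.
#' @param inversions number of inversions per branch.
#' @param inversion_size inclusive range (genes) of inversion lengths.
#' @param translocations number of translocations per branch.
#' @param translocation_size translocated segment length (genes).
#' @param tandem_rate per-gene probability of gaining one adjacent tandem
#'   copy on a branch.
#' @param loss_rate per-gene deletion probability on a branch.
#' @param wgd_before_split duplicate the whole ancestral genome before the
#'   genomes split?
#' @param bitscore_mean,bitscore_sd Normal parameters of ortholog bitscores.
#' @param paralog_decay multiplier (< 1) applied to the bitscore mean of
#'   pairs related only through the pre-split whole-genome duplication,
#'   emulating the score gap between primary orthologs and older paralogs.
#' @param spurious_rate number of random low-score hits per pair, as a
#'   fraction of the true homolog-pair count.
#' @param seed integer seed fixing every draw.
#' @param tree optional explicit tree: list of branches, each
#'   `list(parent =, child =, events = list(...))` with event fields as
#'   above plus `wgd`. Overrides the star construction.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(genomes = c("genA", "genB", "genC"),
                         n_chrom = 2L, genes_per_chrom = 500L,
                         inversions = 2L, inversion_size = c(20L, 50L),
                         translocations = 1L, translocation_size = 20L,
                         tandem_rate = 0.01, loss_rate = 0.02,
                         wgd_before_split = FALSE,
                         bitscore_mean = 500, bitscore_sd = 30,
                         paralog_decay = 0.7, spurious_rate = 0.01,
                         seed = 42L, tree = NULL) {
  stopifnot(n_chrom >= 1L, genes_per_chrom >= 1L,
            tandem_rate >= 0, tandem_rate <= 1,
            loss_rate >= 0, loss_rate <= 1,
            spurious_rate >= 0, spurious_rate <= 1,
            paralog_decay > 0, paralog_decay <= 1)
  if (is.null(tree)) {
    root <- "anc"
    tree <- list()
    branch_events <- list(
      inversions = as.integer(inversions),
      inversion_size = as.integer(inversion_size),
      translocations = as.integer(translocations),
      translocation_size = as.integer(translocation_size),
      tandem_rate = tandem_rate, loss_rate = loss_rate, wgd = FALSE)
    parent <- root
    if (wgd_before_split) {
      tree[[1L]] <- list(parent = root, child = "anc_wgd",
                         events = list(inversions = 0L,
                                       inversion_size = c(1L, 1L),
                                       translocations = 0L,
                                       translocation_size = 1L,
                                       tandem_rate = 0, loss_rate = 0,
                                       wgd = TRUE))
      parent <- "anc_wgd"
    }
    for (g in genomes)
      tree[[length(tree) + 1L]] <- list(parent = parent, child = g,
                                        events = branch_events)
  }
  structure(list(genomes = genomes, n_chrom = as.integer(n_chrom),
                 genes_per_chrom = as.integer(genes_per_chrom),
                 tree = tree,
                 noise = list(bitscore_mean = bitscore_mean,
                              bitscore_sd = bitscore_sd,
                              paralog_decay = paralog_decay,
                              spurious_rate = spurious_rate),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate the ancestral genome of a scenario
#'
#' @param scenario [sim_scenario()].
#' @return internal genome state: `data.table` (gene_id, anc, sub, chrom,
#'   strand) in gene order, with `anc` the ancestral gene id and `sub` the
#'   subgenome label (1 until a whole-genome duplication creates 2).
#' @export
simulate_ancestor <- function(scenario) {
  nc <- scenario$n_chrom; np <- scenario$genes_per_chrom
  ids <- sprintf("anc_c%d_%04d", rep(seq_len(nc), each = np),
                 rep(seq_len(np), nc))
  data.table::data.table(
    gene_id = ids, anc = ids, sub = 1L,
    chrom = sprintf("chr%d", rep(seq_len(nc), each = np)),
    strand = "+")
}

#' Evolve one branch of a scenario tree
#'
#' Applies, in order: whole-genome duplication (chromosomes duplicated with
#' a `_2` suffix and a new subgenome label), the segmental events
#' (inversions and translocations, applied sequentially in a seeded random
#' order), tandem duplications, then gene losses. Draws come from the
#' current RNG stream.
#'
#' @param state parent genome state (see [simulate_ancestor()]).
#' @param events event list (fields as in [sim_scenario()]'s branches).
#' @param child child genome name (stamped into new gene ids).
#' @return list with `state` (child genome state) and `map` (a `data.table`
#'   parent_gene, child_gene, relation in {ortholog, wgd_paralog,
#'   tandem_paralog, lost}; total over parent genes).
#' @export
evolve_branch <- function(state, events, child) {
  g <- data.table::copy(state)
  rel <- stats::setNames(rep("ortholog", nrow(g)), g$gene_id)
  parent_of <- stats::setNames(g$gene_id, g$gene_id)
  if (isTRUE(events$wgd)) {
    dup <- data.table::copy(g)
    dup[, "chrom" := paste0(dup$chrom, "_2")]
    dup[, "sub" := dup$sub + max(g$sub)]
    dup_ids <- paste0(dup$gene_id, "|w")
    parent_of <- c(parent_of, stats::setNames(dup$gene_id, dup_ids))
    rel <- c(rel, stats::setNames(rep("wgd_paralog", nrow(dup)), dup_ids))
    dup[, "gene_id" := dup_ids]
    g <- data.table::rbindlist(list(g, dup))
  }
  # per-chromosome ordered index lists
  st <- split(seq_len(nrow(g)), g$chrom)
  st <- st[order(names(st))]
  flip <- rep(FALSE, nrow(g))
  seg_events <- c(rep("inversion", events$inversions %||% 0L),
                  rep("translocation", events$translocations %||% 0L))
  if (length(seg_events) > 1L) seg_events <- sample(seg_events)
  for (ev in seg_events) {
    lens <- vapply(st, length, integer(1))
    if (ev == "inversion") {
      szr <- events$inversion_size[1L]:events$inversion_size[2L]
      sz <- szr[sample.int(length(szr), 1L)]
      ok <- which(lens > sz)
      if (!length(ok)) next
      ch <- ok[sample.int(length(ok), 1L, prob = lens[ok])]
      s <- sample.int(lens[ch] - sz + 1L, 1L)
      seg <- st[[ch]][s:(s + sz - 1L)]
      st[[ch]][s:(s + sz - 1L)] <- rev(seg)
      flip[seg] <- !flip[seg]
    } else {
      sz <- events$translocation_size
      ok <- which(lens > sz)
      if (length(ok) < 1L || length(st) < 2L) next
      ch <- ok[sample.int(length(ok), 1L, prob = lens[ok])]
      s <- sample.int(lens[ch] - sz + 1L, 1L)
      seg <- st[[ch]][s:(s + sz - 1L)]
      st[[ch]] <- st[[ch]][-(s:(s + sz - 1L))]
      dchoice <- setdiff(seq_along(st), ch)
      dest <- dchoice[sample.int(length(dchoice), 1L)]
      at <- sample.int(length(st[[dest]]) + 1L, 1L)
      st[[dest]] <- append(st[[dest]], seg, after = at - 1L)
    }
  }
  # tandem duplications: sampled genes gain one adjacent copy
  tr <- events$tandem_rate %||% 0
  tandem_of <- integer(0)
  if (tr > 0) {
    ndup <- stats::rbinom(1L, nrow(g), tr)
    if (ndup > 0L) tandem_of <- sort(sample.int(nrow(g), ndup))
  }
  # losses
  lr <- events$loss_rate %||% 0
  lost <- rep(FALSE, nrow(g))
  if (lr > 0) {
    nl <- stats::rbinom(1L, nrow(g), lr)
    if (nl > 0L) lost[sample.int(nrow(g), nl)] <- TRUE
  }
  # materialize the child in final (chrom, position) order
  rows <- list(); relation <- list()
  for (ch in names(st)) {
    for (i in st[[ch]]) {
      if (!lost[i]) {
        rows[[length(rows) + 1L]] <-
          list(old = i, chrom = ch, tandem = FALSE)
        if (i %in% tandem_of)
          rows[[length(rows) + 1L]] <-
            list(old = i, chrom = ch, tandem = TRUE)
      }
    }
  }
  old <- vapply(rows, `[[`, integer(1), "old")
  tand <- vapply(rows, `[[`, logical(1), "tandem")
  chv <- vapply(rows, `[[`, character(1), "chrom")
  child_ids <- sprintf("%s_%05d", child, seq_along(old))
  out <- data.table::data.table(
    gene_id = child_ids,
    anc = g$anc[old], sub = g$sub[old], chrom = chv,
    strand = ifelse(xor(g$strand[old] == "-", flip[old]), "-", "+"))
  map <- data.table::data.table(
    parent_gene = unname(parent_of[g$gene_id[old]]),
    child_gene = child_ids,
    relation = ifelse(tand, "tandem_paralog", unname(rel[g$gene_id[old]])))
  if (any(lost)) {
    lost_idx <- which(lost)
    map <- data.table::rbindlist(list(map, data.table::data.table(
      parent_gene = unname(parent_of[g$gene_id[lost_idx]]),
      child_gene = NA_character_, relation = "lost")))
  }
  list(state = out, map = map)
}

# internal: genome state -> annotation-shaped gene table (3 kb genes on a
# 5 kb grid; only rank order matters downstream)
state_to_genes <- function(state, genome) {
  s <- data.table::copy(state)
  pos <- stats::ave(seq_len(nrow(s)), s$chrom, FUN = seq_along)
  dt <- data.table::data.table(
    gene_id = s$gene_id, chrom = s$chrom,
    start = (pos - 1L) * 5000L, end = (pos - 1L) * 5000L + 3000L,
    strand = s$strand)
  normalize_genes(dt, genome)
}

#' Simulate a full multi-genome dataset with ground truth
#'
#' Runs the scenario tree from the ancestral genome, producing per-genome
#' annotations, truth tables (ancestral gene and subgenome of every gene),
#' truth orthogroups (connected components of the descent relation, i.e.
#' genes sharing an ancestral root gene), and noisy pairwise hit tables for
#' every genome pair (intragenomic tables included when they are non-empty).
#'
#' @param scenario [sim_scenario()].
#' @return object of class `genome_sim`: list(scenario, genomes, truth,
#'   og_truth, hits, branch_maps).
#' @export
simulate_genomes <- function(scenario) {
  set.seed(scenario$seed)
  states <- list()
  root <- scenario$tree[[1L]]$parent
  states[[root]] <- simulate_ancestor(scenario)
  branch_maps <- list()
  for (br in scenario$tree) {
    if (is.null(states[[br$parent]]))
      stop("tree branch parent '", br$parent, "' not yet simulated")
    res <- evolve_branch(states[[br$parent]], br$events, br$child)
    states[[br$child]] <- res$state
    branch_maps[[paste(br$parent, br$child, sep = "->")]] <- res$map
  }
  leaves <- scenario$genomes
  genomes <- lapply(leaves, function(g) state_to_genes(states[[g]], g))
  names(genomes) <- leaves
  truth <- data.table::rbindlist(lapply(leaves, function(g) {
    s <- states[[g]]
    data.table::data.table(gene_id = s$gene_id, genome = g, anc = s$anc,
                           sub = s$sub)
  }))
  ancs <- sort(unique(truth$anc))
  og_lab <- stats::setNames(sprintf("OG%05d", seq_along(ancs)), ancs)
  og_truth <- stats::setNames(unname(og_lab[truth$anc]), truth$gene_id)
  sim <- structure(list(scenario = scenario, genomes = genomes,
                        truth = truth, og_truth = og_truth,
                        branch_maps = branch_maps, hits = list()),
                   class = "genome_sim")
  for (i in seq_along(leaves)) {
    for (j in i:length(leaves)) {
      ht <- emit_hits(sim, leaves[[i]], leaves[[j]])
      if (!is.null(ht) && nrow(ht))
        sim$hits[[paste(leaves[[i]], leaves[[j]], sep = "__")]] <- ht
    }
  }
  sim
}

#' Emit a noisy similarity-hit table for a genome pair
#'
#' Every pair of genes sharing an ancestral root gene gets a hit with
#' bitscore drawn from Normal(mean, sd) (truncated positive); pairs related
#' only through a pre-split whole-genome duplication (different subgenome
#' labels) have the mean multiplied by `paralog_decay`. Spurious random
#' pairs are added at `spurious_rate` with low scores. Percent identity is
#' a monotone transform of bitscore. Intragenomic calls omit self pairs and
#' keep one orientation per unordered pair. Draws come from the current RNG
#' stream; [simulate_genomes()] calls this under the scenario seed and
#' caches the result in `$hits`.
#'
#' @param sim `genome_sim` object (or a partially built one with `truth`).
#' @param genomeA,genomeB genome names.
#' @return `data.table` (query = genomeA gene, target = genomeB gene,
#'   pident, bitscore), or NULL when no pairs exist.
#' @export
emit_hits <- function(sim, genomeA, genomeB) {
  no <- sim$scenario$noise
  ta <- sim$truth[sim$truth$genome == genomeA,
                  c("gene_id", "anc", "sub")]
  tb <- sim$truth[sim$truth$genome == genomeB,
                  c("gene_id", "anc", "sub")]
  m <- merge(ta, tb, by = "anc", allow.cartesian = TRUE,
             suffixes = c(".q", ".t"))
  if (genomeA == genomeB) {
    m <- m[m$gene_id.q < m$gene_id.t]
  }
  if (!nrow(m)) return(NULL)
  data.table::setorderv(m, c("gene_id.q", "gene_id.t"))
  cross <- m$sub.q != m$sub.t
  mu <- no$bitscore_mean * ifelse(cross, no$paralog_decay, 1)
  bs <- pmax(1, stats::rnorm(nrow(m), mu, no$bitscore_sd))
  hits <- data.table::data.table(query = m$gene_id.q, target = m$gene_id.t,
                                 bitscore = bs)
  nsp <- round(no$spurious_rate * nrow(m))
  if (nsp > 0L) {
    sq <- ta$gene_id[sample.int(nrow(ta), nsp, replace = TRUE)]
    stg <- tb$gene_id[sample.int(nrow(tb), nsp, replace = TRUE)]
    keep <- sq != stg
    sp <- data.table::data.table(
      query = sq[keep], target = stg[keep],
      bitscore = pmax(1, stats::rnorm(sum(keep), 0.2 * no$bitscore_mean,
                                      no$bitscore_sd)))
    hits <- data.table::rbindlist(list(hits, sp))
  }
  hits[, "bitscore" := round(hits$bitscore, 1)]
  hits[, "pident" := round(pmin(99.9, pmax(
    15, 100 * hits$bitscore / (no$bitscore_mean * 1.2))), 1)]
  data.table::setorderv(hits, c("query", "target", "bitscore"),
                        order = c(1L, 1L, -1L))
  hits <- unique(hits, by = c("query", "target"))
  data.table::setcolorder(hits, c("query", "target", "pident", "bitscore"))
  data.table::setattr(hits, "genomeQ", genomeA)
  data.table::setattr(hits, "genomeT", genomeB)
  hits[]
}

#' Write a simulated dataset to disk as standard-format fixtures
#'
#' Emits, per genome, a GFF3 and a BED annotation; a truth orthogroups TSV
#' (Orthogroups.tsv dialect); one 12-column outfmt-6 hit TSV per genome
#' pair; and an event-log JSON recording the scenario (replaying it through
#' [simulate_genomes()] regenerates identical genomes). Everything loads
#' back through the package's readers unchanged.
#'
#' @param sim `genome_sim` object.
#' @param outdir output directory.
#' @param force overwrite a non-empty directory?
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(sim, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory exists and is not empty: ", outdir,
         " (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(sim$genomes)) {
    write_annotation_gff3(sim$genomes[[g]],
                          file.path(outdir, paste0(g, ".gff3")))
    write_annotation_bed(sim$genomes[[g]],
                         file.path(outdir, paste0(g, ".bed")))
  }
  write_orthogroups(sim$og_truth, sim$genomes,
                    file.path(outdir, "orthogroups.tsv"))
  for (nm in names(sim$hits)) {
    h <- sim$hits[[nm]]
    out <- data.table::data.table(
      qseqid = h$query, sseqid = h$target, pident = h$pident,
      length = 300L, mismatch = 0L, gapopen = 0L, qstart = 1L,
      qend = 300L, sstart = 1L, send = 300L, evalue = "1e-50",
      bitscore = h$bitscore)
    data.table::fwrite(out, file.path(outdir, paste0("hits_", nm, ".tsv")),
                       sep = "\t", col.names = FALSE)
  }
  log <- list(scenario = unclass(sim$scenario),
              n_genes = vapply(sim$genomes, nrow, integer(1)))
  jsonlite::write_json(log, file.path(outdir, "events.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Rebuild a simulation from a fixture's event log
#'
#' @param path path to the `events.json` written by [write_fixture()].
#' @return the regenerated `genome_sim` object.
#' @export
replay_fixture <- function(path) {
  log <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc <- log$scenario
  tree <- lapply(sc$tree, function(br) {
    ev <- br$events
    list(parent = br$parent, child = br$child,
         events = list(
           inversions = as.integer(ev$inversions),
           inversion_size = as.integer(unlist(ev$inversion_size)),
           translocations = as.integer(ev$translocations),
           translocation_size = as.integer(ev$translocation_size),
           tandem_rate = as.numeric(ev$tandem_rate),
           loss_rate = as.numeric(ev$loss_rate),
           wgd = isTRUE(ev$wgd)))
  })
  scen <- sim_scenario(genomes = unlist(sc$genomes), n_chrom = sc$n_chrom,
                       genes_per_chrom = sc$genes_per_chrom,
                       bitscore_mean = sc$noise$bitscore_mean,
                       bitscore_sd = sc$noise$bitscore_sd,
                       paralog_decay = sc$noise$paralog_decay,
                       spurious_rate = sc$noise$spurious_rate,
                       seed = sc$seed, tree = tree)
  simulate_genomes(scen)
}

#' @export
print.genome_sim <- function(x, ...) {
  cat("Simulated dataset:", length(x$genomes), "genomes, seed",
      x$scenario$seed, "\n")
  for (g in names(x$genomes))
    cat(sprintf("  %s: %d genes on %d chromosomes\n", g,
                nrow(x$genomes[[g]]), length(unique(x$genomes[[g]]$chrom))))
  cat("  truth orthogroups:", length(unique(x$og_truth)), "\n")
  invisible(x)
}
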