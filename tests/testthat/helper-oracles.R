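# Shared fixtures and independent oracles, built in code at test time.

# Quick gene-table builder: one genome, genes given as a data.frame with
# chrom/start/end (and optional gene_id, strand).
toy_genes <- function(chrom, start, end = start + 100L, gene_id = NULL,
                      strand = "+", genome = "gA") {
  n <- length(chrom)
  dt <- data.table::data.table(
    gene_id = gene_id %||% sprintf("%s_g%03d", genome, seq_len(n)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = rep(strand, length.out = n))
  synpan:::normalize_genes(dt, genome)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Raw hit table with the attributes run_synteny expects.
toy_hits <- function(query, target, bitscore, genomeQ, genomeT,
                     pident = NULL) {
  h <- data.table::data.table(
    query = query, target = target,
    pident = pident %||% pmin(99.9, bitscore / 6),
    bitscore = as.numeric(bitscore))
  data.table::setattr(h, "genomeQ", genomeQ)
  data.table::setattr(h, "genomeT", genomeT)
  h
}

# Exhaustive-search oracle for the best collinear chain score: enumerates
# every valid chain (strict monotonicity, per-axis gap cap) by depth-first
# extension. Independent of the DP in the package.
brute_best_chain_score <- function(x, y, nGaps) {
  n <- length(x)
  best <- 0L
  extend <- function(i, len, sgn) {
    best <<- max(best, len)
    for (j in seq_len(n)) {
      dx <- x[j] - x[i]
      dy <- sgn * (y[j] - y[i])
      if (dx >= 1 && dy >= 1 && (dx - 1) <= nGaps && (dy - 1) <= nGaps)
        extend(j, len + 1L, sgn)
    }
  }
  for (sgn in c(1, -1)) for (i in seq_len(n)) extend(i, 1L, sgn)
  best
}

# Brute-force tandem-array oracle: split sorted member ranks wherever the
# adjacent gap exceeds synBuff; clusters of >= 2 are arrays. Returns the
# list of member-ord clusters.
gap_split_oracle <- function(ords, synBuff) {
  o <- sort(ords)
  cl <- cumsum(c(1L, as.integer(diff(o) > synBuff)))
  unname(split(o, cl))
}

# Median-rule representative oracle (ties: longest peptide, then smallest
# gene id), written independently of the package's pick.
rep_oracle <- function(ids, ords, plen = NULL) {
  d <- abs(ords - stats::median(ords))
  cand <- which(d == min(d))
  if (length(cand) > 1L && !is.null(plen)) {
    pv <- plen[ids[cand]]
    pv[is.na(pv)] <- -Inf
    cand <- cand[pv == max(pv)]
  }
  ids[cand][order(ids[cand])][1L]
}

# Small simulated dataset reused by several module tests (kept small so the
# default suite stays fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_scenario(genomes = c("gA", "gB"), n_chrom = 2L,
                         genes_per_chrom = 150L, inversions = 1L,
                         inversion_size = c(15L, 25L), translocations = 0L,
                         tandem_rate = 0.01, loss_rate = 0.02, seed = 301L)
      cache <<- simulate_genomes(sc)
    }
    cache
  }
})
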