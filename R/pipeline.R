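#' Run the full synteny pipeline over a set of genomes
#'
#' Orchestrates the whole scan: chromosome QC, tandem-array detection and
#' array rank assignment per genome, then for every genome pair with a hit
#' table the anchor/block cascade; optional self-synteny per genome,
#' optional in-block orthogroup refinement (rerunning the scan once with
#' the combined labels), and optional secondary (paralog) scans. Genomes
#' listed in `params$outgroups` contribute orthogroup evidence only and are
#' excluded from every downstream stage.
#'
#' @param genomes named list of gene tables from [read_annotation()].
#' @param hits list of raw hit tables from [read_hits()] (or
#'   [emit_hits()]); genome pair read from each table's attributes.
#'   Intragenomic tables drive the self-synteny scans.
#' @param og_map named vector gene_id -> orthogroup id
#'   ([read_orthogroups()]), or NULL to derive orthogroups internally from
#'   reciprocal best hits across each pair.
#' @param params [synteny_params()].
#' @param peptide_lengths optional named vector for tandem-representative
#'   tie-breaking.
#' @param include_self also compute self-synteny blocks per genome?
#' @return object of class `synteny_scan`: list(genes, genomes, pairs,
#'   self, params, used_in_block_og).
#' @export
run_synteny <- function(genomes, hits, og_map = NULL,
                        params = synteny_params(),
                        peptide_lengths = NULL, include_self = FALSE) {
  stopifnot(is.list(genomes), length(names(genomes)) == length(genomes))
  core <- setdiff(names(genomes), params$outgroups)
  if (!length(core)) stop("no genomes left after outgroup exclusion")
  if (is.null(og_map)) og_map <- rbh_orthogroups(hits)
  prep <- lapply(genomes[core], function(g) {
    g <- qc_chromosomes(g, params)
    g <- assign_orthogroups(g, og_map)
    find_tandem_arrays(g, params, peptide_lengths)
  })
  genes_list <- lapply(prep, `[[`, "genes")
  arrays <- data.table::rbindlist(lapply(prep, `[[`, "arrays"))
  run_pairs <- function(genes_list) {
    pairs <- list()
    selfres <- list()
    for (ht in hits) {
      gq <- attr(ht, "genomeQ", exact = TRUE)
      gt <- attr(ht, "genomeT", exact = TRUE)
      if (is.null(gq) || is.null(gt))
        stop("hit tables must carry genomeQ/genomeT attributes ",
             "(use read_hits() or emit_hits())")
      if (!(gq %in% core) || !(gt %in% core)) next
      ah <- annotate_hits(ht, genes_list[[gq]], genes_list[[gt]])
      if (gq == gt) {
        if (include_self || ploidy_of(params, gq) > 1L)
          selfres[[gq]] <- self_synteny(genes_list[[gq]], params, ah)
        next
      }
      res <- synteny_pair(ah, params, gq, gt)
      if (params$nSecondaryHits > 0L) {
        sec <- secondary_hits_scan(res, params, gq, gt)
        if (!is.null(sec)) res$secondary <- sec
      }
      pairs[[paste(gq, gt, sep = "__")]] <- res
    }
    if (include_self) {
      for (g in setdiff(core, names(selfres)))
        selfres[[g]] <- self_synteny(genes_list[[g]], params)
    }
    list(pairs = pairs, self = selfres)
  }
  res <- run_pairs(genes_list)
  # in-block orthogroup refinement: rerun the scan once with combined labels
  in_blk <- params$orthofinderInBlk
  if (is.na(in_blk))
    in_blk <- any(vapply(core, function(g) ploidy_of(params, g) > 1L,
                         logical(1)))
  used_in_block <- FALSE
  if (isTRUE(in_blk) && length(res$pairs)) {
    iog <- in_block_orthogroups(res$pairs)
    if (length(iog)) {
      combined <- og_map
      combined[names(iog)] <- unname(iog)
      genes_list <- lapply(genes_list, function(g) {
        g <- assign_orthogroups(g, combined)
        # arrays were called on global orthogroups; array structure is kept
        g
      })
      res <- run_pairs(genes_list)
      used_in_block <- TRUE
      og_map <- combined
    }
  }
  genes <- data.table::rbindlist(genes_list)
  structure(list(genes = genes, genomes = genes_list, pairs = res$pairs,
                 self = res$self, arrays = arrays, params = params,
                 og_map = og_map, used_in_block_og = used_in_block),
            class = "synteny_scan")
}

# Fallback orthogrouping when no orthogroup file is given: connected
# components of the reciprocal-best-hit graph across every genome pair
# (per pair, a hit is an RBH edge when it is top-scoring for both genes).
rbh_orthogroups <- function(hits) {
  eq <- character(0); et <- character(0)
  for (ht in hits) {
    gq <- attr(ht, "genomeQ", exact = TRUE)
    gt <- attr(ht, "genomeT", exact = TRUE)
    if (identical(gq, gt)) next
    bq <- stats::ave(ht$bitscore, ht$query, FUN = max)
    bt <- stats::ave(ht$bitscore, ht$target, FUN = max)
    rbh <- ht$bitscore >= bq & ht$bitscore >= bt
    eq <- c(eq, ht$query[rbh]); et <- c(et, ht$target[rbh])
  }
  if (!length(eq)) return(stats::setNames(character(0), character(0)))
  g <- igraph::graph_from_data_frame(data.frame(from = eq, to = et),
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  first_gene <- tapply(names(comp), comp, min)
  relab <- stats::setNames(sprintf("OG%06d", rank(first_gene)),
                           names(first_gene))
  stats::setNames(unname(relab[as.character(comp)]), names(comp))
}

# locate the pair result between two genomes, either orientation
find_pair <- function(scan, a, b) {
  scan$pairs[[paste(a, b, sep = "__")]] %||%
    scan$pairs[[paste(b, a, sep = "__")]]
}

#' Collect all blocks of a scan into one table
#' @param scan `synteny_scan` object.
#' @param include_self,include_secondary include self-synteny / secondary
#'   blocks?
#' @return `data.table` of blocks.
#' @export
scan_blocks <- function(scan, include_self = TRUE,
                        include_secondary = TRUE) {
  out <- list()
  for (pr in scan$pairs) {
    out[[length(out) + 1L]] <- pr$blocks
    if (include_secondary && !is.null(pr$secondary))
      out[[length(out) + 1L]] <- pr$secondary$blocks
  }
  if (include_self)
    for (sr in scan$self) out[[length(out) + 1L]] <- sr$blocks
  if (!length(out)) return(empty_block_table())
  data.table::rbindlist(out)
}

#' @export
print.synteny_scan <- function(x, ...) {
  cat("Synteny scan:", length(x$genomes), "genomes,",
      length(x$pairs), "genome pairs\n")
  blocks <- scan_blocks(x, include_self = FALSE, include_secondary = FALSE)
  cat("  primary blocks:", nrow(blocks), "\n")
  for (pr_name in names(x$pairs)) {
    pr <- x$pairs[[pr_name]]
    nanch <- sum(pr$hits$isAnchor)
    cat(sprintf("  %s: %d blocks, %d anchors, %d in-buffer hits\n",
                sub("__", " vs ", pr_name), nrow(pr$blocks), nanch,
                sum(pr$hits$inBuffer)))
    if (!is.null(pr$secondary))
      cat(sprintf("    secondary: %d blocks\n", nrow(pr$secondary$blocks)))
  }
  if (isTRUE(x$used_in_block_og))
    cat("  orthogroups refined within syntenic regions\n")
  invisible(x)
}

#' @export
summary.synteny_scan <- function(object, ...) {
  blocks <- scan_blocks(object, include_self = FALSE,
                        include_secondary = FALSE)
  out <- list(
    n_genomes = length(object$genomes),
    n_pairs = length(object$pairs),
    n_blocks = nrow(blocks),
    n_arrays = nrow(object$arrays),
    anchors_per_pair = vapply(object$pairs,
                              function(p) sum(p$hits$isAnchor), numeric(1)),
    median_block_anchors = if (nrow(blocks))
      stats::median(blocks$n_anchors) else NA_real_)
  class(out) <- "summary.synteny_scan"
  out
}

#' @export
print.summary.synteny_scan <- function(x, ...) {
  cat("Synteny scan summary\n")
  cat("  genomes:", x$n_genomes, " pairs:", x$n_pairs, "\n")
  cat("  primary blocks:", x$n_blocks,
      " (median anchors/block:", x$median_block_anchors, ")\n")
  cat("  tandem arrays:", x$n_arrays, "\n")
  if (length(x$anchors_per_pair)) {
    cat("  anchors per pair:\n")
    print(x$anchors_per_pair)
  }
  invisible(x)
}

#' Write the principal scan outputs as TSV
#'
#' Emits deterministic, byte-stable tables: blocks, annotated hits per
#' pair, tandem arrays, and per-genome block-coordinate BED files.
#'
#' @param scan `synteny_scan` object.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_scan <- function(scan, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  blocks <- scan_blocks(scan)
  data.table::setorderv(blocks, c("genomeQ", "genomeT", "chromQ", "chromT",
                                  "blk_id"))
  data.table::fwrite(blocks, file.path(outdir, "blocks.tsv"), sep = "\t")
  for (nm in names(scan$pairs)) {
    h <- data.table::copy(scan$pairs[[nm]]$hits)
    data.table::setorderv(h, c("query", "target"))
    data.table::fwrite(h, file.path(outdir, paste0("hits_", nm, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(scan$arrays, file.path(outdir, "tandem_arrays.tsv"),
                     sep = "\t")
  for (g in names(scan$genomes)) {
    b <- blocks[blocks$genomeQ == g & !blocks$is_self]
    if (!nrow(b)) next
    bed <- data.table::data.table(chrom = b$chromQ, start = b$startQ,
                                  end = b$endQ, name = b$blk_id)
    data.table::setorderv(bed, c("chrom", "start", "end", "name"))
    data.table::fwrite(bed, file.path(outdir, paste0(g, "_blocks.bed")),
                       sep = "\t", col.names = FALSE)
  }
  invisible(outdir)
}

#' Write the pan-genome annotation as TSV
#'
#' @param pg `pangenome` object.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pangenome <- function(pg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(pg$long, file.path(outdir, "pangenome_long.tsv"),
                     sep = "\t")
  data.table::fwrite(pg$wide, file.path(outdir, "pangenome_wide.tsv"),
                     sep = "\t")
  pav <- data.table::as.data.table(pg$pav, keep.rownames = "pgID")
  cnv <- data.table::as.data.table(pg$cnv, keep.rownames = "pgID")
  data.table::fwrite(pav, file.path(outdir, "pav.tsv"), sep = "\t")
  data.table::fwrite(cnv, file.path(outdir, "cnv.tsv"), sep = "\t")
  sogw <- pg$sogs[, list(members = paste(sort(gene_id), collapse = ",")),
                  by = c("sog_id", "genome")]
  sogw <- data.table::dcast(sogw, sog_id ~ genome, value.var = "members",
                            fill = "")
  data.table::fwrite(sogw, file.path(outdir, "syntenic_orthogroups.tsv"),
                     sep = "\t")
  invisible(outdir)
}
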