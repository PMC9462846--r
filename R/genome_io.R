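#' Read a gene annotation into a normalized gene table
#'
#' Parses GFF3 (via \code{rtracklayer::readGFF}) or BED (4+ columns), keeps
#' one record per primary gene model, and assigns the within-chromosome gene
#' rank order (`ord`) that all downstream synteny inference runs on.
#' Coordinates are stored 0-based half-open internally; GFF3 input (1-based
#' closed) is converted on load.
#'
#' @param path path to a GFF3 or BED file.
#' @param genome genome name to attach to every record.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param gff_feature GFF3 feature type holding the primary gene models
#'   (usually `"gene"`, sometimes `"mRNA"`).
#'
#' @return a `data.table` with columns gene_id, genome, chrom, start, end,
#'   strand, ord, og, is_array_rep, array_id, array_ord. Rows are sorted by
#'   (chrom, start); `ord` is 1..n per chromosome with ties on start broken
#'   by end, then gene_id.
#' @export
read_annotation <- function(path, genome, format = c("auto", "gff3", "bed"),
                            gff_feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  if (format == "gff3") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    g <- g[g$type == gff_feature, , drop = FALSE]
    if (!nrow(g)) stop("no '", gff_feature, "' features in ", path)
    id <- as.character(g$ID)
    if (any(is.na(id) | id == ""))
      stop("GFF3 gene records must carry an ID attribute: ", path)
    dt <- data.table::data.table(
      gene_id = id,
      chrom = as.character(g$seqid),
      start = as.integer(g$start) - 1L,  # 1-based closed -> 0-based half-open
      end = as.integer(g$end),
      strand = as.character(g$strand)
    )
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1L))
    if (ncol(dt) < 4L) stop("BED input needs >= 4 columns: ", path)
    dt <- data.table::data.table(
      gene_id = as.character(dt[[4L]]),
      chrom = as.character(dt[[1L]]),
      start = as.integer(dt[[2L]]),
      end = as.integer(dt[[3L]]),
      strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."
    )
  }
  dt[is.na(dt$strand) | !(dt$strand %in% c("+", "-")), "strand"] <- "."
  normalize_genes(dt, genome)
}

# Sorts, validates and rank-orders a raw gene table.
normalize_genes <- function(dt, genome) {
  gene_id <- chrom <- start <- NULL
  if (!nrow(dt)) stop("annotation for genome '", genome, "' has zero genes")
  if (anyDuplicated(dt$gene_id))
    stop("duplicate gene_id in genome '", genome, "': ",
         dt$gene_id[duplicated(dt$gene_id)][1L])
  if (any(dt$start >= dt$end))
    stop("gene with start >= end in genome '", genome, "'")
  dt <- data.table::copy(dt)
  dt[, "genome" := genome]
  data.table::setorderv(dt, c("chrom", "start", "end", "gene_id"))
  dt[, "ord" := seq_len(.N), by = "chrom"]
  dt[, "og" := NA_character_]
  dt[, "is_array_rep" := NA]
  dt[, "array_id" := NA_character_]
  dt[, "array_ord" := NA_integer_]
  data.table::setcolorder(dt, c("gene_id", "genome", "chrom", "start", "end",
                                "strand", "ord", "og", "is_array_rep",
                                "array_id", "array_ord"))
  dt[]
}

#' Drop chromosomes too small for synteny inference
#'
#' Chromosomes carrying fewer than `blkSize` genes cannot host a syntenic
#' block and are removed before inference. Per-chromosome gene ranks are
#' unaffected (ranks are never shared across chromosomes).
#'
#' @param genes gene table from [read_annotation()].
#' @param params [synteny_params()].
#' @return the filtered gene table; the gene ids removed are attached as
#'   attribute `"dropped"`.
#' @export
qc_chromosomes <- function(genes, params = synteny_params()) {
  stopifnot(is.data.frame(genes))
  n <- NULL
  cnt <- genes[, list(n = .N), by = c("genome", "chrom")]
  bad <- cnt[cnt$n < params$blkSize]
  if (!nrow(bad)) {
    out <- data.table::copy(genes)
    data.table::setattr(out, "dropped", character(0))
    return(out[])
  }
  key <- paste(genes$genome, genes$chrom)
  drop <- key %in% paste(bad$genome, bad$chrom)
  out <- genes[!drop]
  gone <- setdiff(unique(genes$genome), unique(out$genome))
  if (length(gone))
    stop("all chromosomes dropped for genome(s): ",
         paste(gone, collapse = ", "))
  data.table::setattr(out, "dropped", genes$gene_id[drop])
  out[]
}

#' Read and merge reciprocal protein-similarity hit files
#'
#' Reads one or two BLAST/DIAMOND tabular (outfmt 6) files for a genome pair
#' and merges them into a single deduplicated hit table. For intergenomic
#' pairs the genome with more gene models is treated as the query; rows from
#' a file oriented the other way are flipped. Duplicated (query, target)
#' pairs keep the row with maximum bitscore (ties: maximum pident, then
#' first occurrence); trivial intragenomic self rows (query == target) are
#' removed.
#'
#' @param paths character vector of 1 or 2 hit-file paths.
#' @param genesQ,genesT gene tables of the two genomes (same table twice for
#'   an intragenomic scan). Which is query is decided by gene-model count.
#' @return a `data.table` with columns query, target, pident, bitscore (plus
#'   genomeQ/genomeT attributes); one row per unique (query, target).
#' @export
read_hits <- function(paths, genesQ, genesT) {
  query <- target <- bitscore <- pident <- NULL
  gq <- genesQ$genome[1L]; gt <- genesT$genome[1L]
  # larger annotation is the query
  if (gq != gt && nrow(genesT) > nrow(genesQ)) {
    tmp <- genesQ; genesQ <- genesT; genesT <- tmp
    gq <- genesQ$genome[1L]; gt <- genesT$genome[1L]
  }
  qset <- genesQ$gene_id; tset <- genesT$gene_id
  tabs <- lapply(paths, function(p) {
    h <- suppressWarnings(data.table::fread(p, header = FALSE, sep = "\t"))
    if (!nrow(h)) stop("empty hit file: ", p)
    if (ncol(h) < 12L) stop("expected 12-column outfmt-6 table: ", p)
    data.table::data.table(query = as.character(h[[1L]]),
                           target = as.character(h[[2L]]),
                           pident = as.numeric(h[[3L]]),
                           bitscore = as.numeric(h[[12L]]))
  })
  hits <- data.table::rbindlist(tabs)
  # orient every row query-genome -> target-genome
  flip <- hits$query %in% tset & hits$target %in% qset &
    !(hits$query %in% qset & hits$target %in% tset)
  if (any(flip)) {
    tmp <- hits$query[flip]
    hits[flip, "query"] <- hits$target[flip]
    hits[flip, "target"] <- tmp
  }
  ok <- hits$query %in% qset & hits$target %in% tset
  n_bad <- sum(!ok)
  if (n_bad > 0.10 * nrow(hits))
    stop(">10% of hit rows reference unknown gene ids (",
         n_bad, "/", nrow(hits), ")")
  hits <- hits[ok]
  hits <- hits[!(gq == gt & hits$query == hits$target)]
  if (!nrow(hits)) stop("no usable hits between ", gq, " and ", gt)
  data.table::setorderv(hits, c("query", "target", "bitscore", "pident"),
                        order = c(1L, 1L, -1L, -1L))
  hits <- unique(hits, by = c("query", "target"))
  data.table::setattr(hits, "genomeQ", gq)
  data.table::setattr(hits, "genomeT", gt)
  if (n_bad) data.table::setattr(hits, "n_unresolved", n_bad)
  hits[]
}

#' Read orthogroup membership (Orthogroups.tsv dialect)
#'
#' First column is the orthogroup id; each remaining column holds a
#' comma-separated member list for one genome. A header line is detected and
#' skipped when its first field looks like a column title ("Orthogroup").
#'
#' @param path TSV path.
#' @return named character vector mapping gene_id -> orthogroup id.
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty orthogroup file: ", path)
  if (grepl("^orthogroup", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  og_ids <- character(0); genes <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    mem <- unlist(strsplit(f[-1L], ",", fixed = TRUE), use.names = FALSE)
    mem <- trimws(mem)
    mem <- mem[nzchar(mem)]
    if (!length(mem)) next
    og_ids <- c(og_ids, rep(f[1L], length(mem)))
    genes <- c(genes, mem)
  }
  if (anyDuplicated(genes)) {
    d <- genes[duplicated(genes)][1L]
    stop("gene listed in more than one orthogroup: ", d)
  }
  stats::setNames(og_ids, genes)
}

#' Attach orthogroup ids to a gene table
#'
#' @param genes gene table.
#' @param og_map named vector from [read_orthogroups()].
#' @return the gene table with `og` filled (NA where unlisted).
#' @export
assign_orthogroups <- function(genes, og_map) {
  out <- data.table::copy(genes)
  out[, "og" := unname(og_map[out$gene_id])]
  out[]
}

#' Write a gene table as GFF3
#'
#' Deterministic writer: rows sorted by (chrom, start), coordinates emitted
#' 1-based closed, gene_id in the ID attribute.
#' @param genes gene table.
#' @param path output path.
#' @export
write_annotation_gff3 <- function(genes, path) {
  g <- data.table::copy(genes)
  data.table::setorderv(g, c("chrom", "start", "end", "gene_id"))
  lines <- sprintf("%s\tsynpan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   g$chrom, g$start + 1L, g$end,
                   ifelse(g$strand %in% c("+", "-"), g$strand, "."),
                   g$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a gene table as BED6
#' @param genes gene table.
#' @param path output path.
#' @export
write_annotation_bed <- function(genes, path) {
  g <- data.table::copy(genes)
  data.table::setorderv(g, c("chrom", "start", "end", "gene_id"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start, g$end,
                   g$gene_id, ifelse(g$strand %in% c("+", "-"), g$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

#' Write orthogroup membership in the Orthogroups.tsv dialect
#' @param og_map named vector gene_id -> orthogroup id.
#' @param genomes named list of gene tables (defines the genome columns).
#' @param path output path.
#' @export
write_orthogroups <- function(og_map, genomes, path) {
  ogs <- sort(unique(unname(og_map)))
  gnames <- names(genomes)
  header <- paste(c("Orthogroup", gnames), collapse = "\t")
  rows <- vapply(ogs, function(og) {
    members <- names(og_map)[og_map == og]
    cols <- vapply(gnames, function(g) {
      m <- sort(members[members %in% genomes[[g]]$gene_id])
      paste(m, collapse = ",")
    }, character(1))
    paste(c(og, cols), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
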