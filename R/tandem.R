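#' Detect tandem arrays and choose representative genes
#'
#' Tandem arrays are clusters of >1 genes from the same orthogroup on the
#' same chromosome whose sorted gene ranks form a chain with no adjacent gap
#' larger than `synBuff` (1-D density clustering; reachability distance
#' `synBuff`, minPts 1). Each array is collapsed to a single representative —
#' the member closest to the array's median rank, ties broken by longest
#' peptide (when lengths are supplied), then by lexicographically smallest
#' gene id — so that tandem copy-number noise cannot masquerade as synteny.
#'
#' @param genes gene table with `og` and `ord` assigned.
#' @param params [synteny_params()] (`synBuff` is the gap threshold).
#' @param peptide_lengths optional named numeric vector, gene_id -> peptide
#'   length, used only for the representative tie-break.
#' @return list with `genes` (the table with is_array_rep / array_id filled;
#'   singletons get is_array_rep = TRUE and no array_id) and `arrays` (a
#'   `data.table`: array_id, genome, chrom, og, n_members, representative,
#'   members comma-joined).
#' @export
find_tandem_arrays <- function(genes, params = synteny_params(),
                               peptide_lengths = NULL) {
  out <- data.table::copy(genes)
  out[, "is_array_rep" := TRUE]
  out[, "array_id" := NA_character_]
  cand <- out[!is.na(out$og)]
  cand <- cand[, if (.N > 1L) .SD, by = c("genome", "chrom", "og"),
               .SDcols = c("gene_id", "ord")]
  arrays <- list()
  if (nrow(cand)) {
    data.table::setorderv(cand, c("genome", "chrom", "og", "ord"))
    grp <- split(cand, by = c("genome", "chrom", "og"), drop = TRUE)
    k <- 0L
    for (gdt in grp) {
      cl <- cumsum(c(1L, diff(gdt$ord) > params$synBuff))
      for (ci in unique(cl)) {
        members <- gdt[cl == ci]
        if (nrow(members) < 2L) next  # singleton cluster: ordinary gene
        k <- k + 1L
        rep_id <- pick_array_rep(members$gene_id, members$ord,
                                 peptide_lengths)
        aid <- sprintf("%s_%s_arr%04d", gdt$genome[1L], gdt$chrom[1L], k)
        arrays[[length(arrays) + 1L]] <- data.table::data.table(
          array_id = aid, genome = gdt$genome[1L], chrom = gdt$chrom[1L],
          og = gdt$og[1L], n_members = nrow(members),
          representative = rep_id,
          members = paste(members$gene_id, collapse = ","))
        idx <- match(members$gene_id, out$gene_id)
        data.table::set(out, idx, "array_id", aid)
        data.table::set(out, idx, "is_array_rep",
                        members$gene_id == rep_id)
      }
    }
  }
  arrays <- if (length(arrays)) data.table::rbindlist(arrays)
  else data.table::data.table(array_id = character(), genome = character(),
                              chrom = character(), og = character(),
                              n_members = integer(),
                              representative = character(),
                              members = character())
  list(genes = assign_array_ord(out), arrays = arrays[])
}

# Representative: member minimizing |ord - median(ord)|; equidistant
# candidates break ties by longest peptide (when lengths are given), then
# by lexicographically smallest gene id.
pick_array_rep <- function(ids, ords, peptide_lengths = NULL) {
  med <- stats::median(ords)
  d <- abs(ords - med)
  best <- which(d == min(d))
  if (length(best) > 1L && !is.null(peptide_lengths)) {
    pl <- peptide_lengths[ids[best]]
    pl[is.na(pl)] <- -Inf
    best <- best[pl == max(pl)]
  }
  if (length(best) > 1L) best <- best[order(ids[best])][1L]
  ids[best[1L]]
}

#' Recompute array rank order over tandem-array representatives
#'
#' `array_ord` is the condensed gene rank among array representatives: per
#' (genome, chromosome), representatives sorted by `ord` get 1..m;
#' non-representative array members get NA. All synteny inference runs in
#' this condensed space so that tandem expansions do not stretch distances.
#'
#' @param genes gene table with `is_array_rep` set.
#' @return the gene table with `array_ord` filled.
#' @export
assign_array_ord <- function(genes) {
  out <- data.table::copy(genes)
  out[, "array_ord" := NA_integer_]
  rep_idx <- which(out$is_array_rep)
  key <- paste(out$genome, out$chrom)
  for (k in unique(key[rep_idx])) {
    i <- rep_idx[key[rep_idx] == k]
    i <- i[order(out$ord[i])]
    data.table::set(out, i, "array_ord", seq_along(i))
  }
  out[]
}
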