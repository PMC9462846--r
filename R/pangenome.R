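#' Interpolate reference rank positions along 1:1 anchor clusters
#'
#' Given the syntenic anchors between one non-reference chromosome and the
#' reference (array-rank coordinates on both sides), anchors are first
#' restricted to ungapped 1:1 runs — consecutive anchors whose ranks step
#' by exactly one on the non-reference axis and by exactly plus or minus
#' one on the reference axis, with a fixed sign and a single reference
#' chromosome per run; any larger jump starts a new cluster. Positions of
#' non-anchor genes are then filled in: inside a cluster's span by linear
#' interpolation between the flanking anchors, outside it by unit-slope
#' extrapolation from the nearest cluster end, provided the gene is within
#' `synBuff` of that end. Genes out of every cluster's reach get NA.
#'
#' @param anchors `data.frame` with columns `t` (non-reference array rank),
#'   `r` (reference array rank) and `ref_chrom`, all anchors of one
#'   non-reference chromosome.
#' @param targets integer vector of non-reference array ranks to position.
#' @param synBuff maximum rank distance from a cluster end for
#'   extrapolation.
#' @return `data.table` with columns `t`, `ref_chrom`, `ref_ord` (NA where
#'   unreachable).
#' @export
interpolate_positions <- function(anchors, targets, synBuff = 100L) {
  out <- data.table::data.table(t = targets, ref_chrom = NA_character_,
                                ref_ord = NA_real_)
  if (is.null(anchors) || !nrow(anchors) || !length(targets)) return(out[])
  a <- data.table::as.data.table(anchors)[order(t, r)]
  a <- unique(a, by = "t")
  dr <- diff(a$r); dt_ <- diff(a$t)
  brk <- dt_ != 1L | abs(dr) != 1L | a$ref_chrom[-1L] != a$ref_chrom[-nrow(a)]
  if (length(dr) > 1L) {
    sgn <- sign(dr)
    brk[-1L] <- brk[-1L] | (sgn[-1L] != sgn[-length(sgn)] &
                              !brk[-length(brk)])
  }
  cl <- cumsum(c(1L, as.integer(brk)))
  clusters <- lapply(split(seq_len(nrow(a)), cl), function(ix) {
    tt <- a$t[ix]; rr <- a$r[ix]
    list(t = tt, r = rr, chrom = a$ref_chrom[ix[1L]],
         tmin = tt[1L], tmax = tt[length(tt)],
         slope = if (length(rr) > 1L) sign(rr[2L] - rr[1L]) else 1)
  })
  for (k in seq_along(targets)) {
    tv <- targets[k]
    best <- NULL; bestd <- Inf; besta <- Inf
    for (cc in clusters) {
      d <- if (tv >= cc$tmin && tv <= cc$tmax) 0
      else min(abs(tv - cc$tmin), abs(tv - cc$tmax))
      da <- min(abs(tv - cc$t))
      if (d < bestd || (d == bestd && da < besta)) {
        best <- cc; bestd <- d; besta <- da
      }
    }
    if (is.null(best) || bestd > synBuff) next
    if (bestd == 0) {
      i2 <- findInterval(tv, best$t)
      if (best$t[i2] == tv) {
        ro <- best$r[i2]
      } else {
        t1 <- best$t[i2]; t2 <- best$t[i2 + 1L]
        r1 <- best$r[i2]; r2 <- best$r[i2 + 1L]
        ro <- r1 + (tv - t1) * (r2 - r1) / (t2 - t1)
      }
    } else if (tv < best$tmin) {
      ro <- best$r[1L] - best$slope * (best$tmin - tv)
    } else {
      ro <- best$r[length(best$r)] + best$slope * (tv - best$tmax)
    }
    data.table::set(out, k, "ref_chrom", best$chrom)
    data.table::set(out, k, "ref_ord", as.numeric(ro))
  }
  out[]
}

# Gather (gene_id, ref_chrom, ref_ord) for every array representative of
# every non-outgroup genome: reference genes at their own positions,
# non-reference representatives interpolated along the primary anchors of
# the (ref, genome) scan.
gene_ref_positions <- function(scan, ref) {
  genes <- scan$genes
  params <- scan$params
  refg <- genes[genes$genome == ref & genes$is_array_rep]
  pos <- list(data.table::data.table(
    gene_id = refg$gene_id, ref_chrom = refg$chrom,
    ref_ord = as.numeric(refg$array_ord)))
  for (g in setdiff(unique(genes$genome), ref)) {
    pr <- find_pair(scan, ref, g)
    if (is.null(pr)) next
    h <- pr$hits
    ref_is_q <- identical(attr(h, "genomeQ", exact = TRUE), ref)
    anc <- h[h$isAnchor]
    gg <- genes[genes$genome == g & genes$is_array_rep]
    for (ch in unique(gg$chrom)) {
      gch <- gg[gg$chrom == ch]
      if (ref_is_q) {
        ach <- anc[anc$chromT == ch]
        adt <- data.table::data.table(t = ach$arrayOrdT, r = ach$arrayOrdQ,
                                      ref_chrom = ach$chromQ)
      } else {
        ach <- anc[anc$chromQ == ch]
        adt <- data.table::data.table(t = ach$arrayOrdQ, r = ach$arrayOrdT,
                                      ref_chrom = ach$chromT)
      }
      ip <- interpolate_positions(adt, gch$array_ord, params$synBuff)
      keep <- !is.na(ip$ref_ord)
      if (any(keep))
        pos[[length(pos) + 1L]] <- data.table::data.table(
          gene_id = gch$gene_id[keep], ref_chrom = ip$ref_chrom[keep],
          ref_ord = ip$ref_ord[keep])
    }
  }
  data.table::rbindlist(pos)
}

#' Place syntenic orthogroups on the reference coordinate system
#'
#' Positions of each syntenic orthogroup's members are split by reference
#' chromosome and then wherever consecutive sorted positions jump by more
#' than `synBuff`. A single-cluster orthogroup is placed directly. A split
#' orthogroup keeps the clusters holding at least `propAssignThresh` of its
#' positioned members (falling back to the single largest cluster when none
#' qualifies), and at most `maxPlacementsPerRefChr` clusters per reference
#' chromosome survive (ranked by member proportion, then size, then lower
#' position). Each kept cluster becomes one pan-genome entry placed at the
#' median position of its members.
#'
#' @param sogs `data.table` (gene_id, genome, sog_id) from
#'   [syntenic_orthogroups()].
#' @param positions `data.table` (gene_id, ref_chrom, ref_ord).
#' @param params [synteny_params()].
#' @return `data.table` of initial entries: pgID, sog_id, ref_chrom,
#'   ref_ord, plus a list-column `members` of directly placed gene ids.
#' @export
place_orthogroups <- function(sogs, positions, params = synteny_params()) {
  sp <- merge(sogs, positions, by = "gene_id")
  entries <- list()
  npg <- 0L
  for (sid in sort(unique(sogs$sog_id))) {
    p <- sp[sp$sog_id == sid]
    if (!nrow(p)) next
    data.table::setorderv(p, c("ref_chrom", "ref_ord", "gene_id"))
    cl <- integer(nrow(p)); cc <- 0L
    for (ch in unique(p$ref_chrom)) {
      ix <- which(p$ref_chrom == ch)
      gaps <- c(FALSE, diff(p$ref_ord[ix]) > params$synBuff)
      cl[ix] <- cc + cumsum(as.integer(gaps)) + 1L
      cc <- max(cl[ix])
    }
    ncl <- length(unique(cl))
    keepcl <- unique(cl)
    if (ncl > 1L) {
      prop <- tabulate(cl)[keepcl] / nrow(p)
      qual <- keepcl[prop >= params$propAssignThresh]
      if (!length(qual)) {
        sizes <- tabulate(cl)[keepcl]
        qual <- keepcl[order(-sizes,
                             vapply(keepcl, function(k)
                               stats::median(p$ref_ord[cl == k]),
                               numeric(1)))][1L]
      }
      # per-chromosome cap
      info <- data.table::data.table(
        cl = qual,
        chrom = vapply(qual, function(k) p$ref_chrom[cl == k][1L],
                       character(1)),
        prop = tabulate(cl)[qual] / nrow(p),
        size = tabulate(cl)[qual],
        med = vapply(qual, function(k) stats::median(p$ref_ord[cl == k]),
                     numeric(1)))
      data.table::setorderv(info, c("chrom", "prop", "size", "med"),
                            order = c(1L, -1L, -1L, 1L))
      info[, "rk" := seq_len(.N), by = "chrom"]
      keepcl <- info$cl[info$rk <= params$maxPlacementsPerRefChr]
    }
    for (k in sort(keepcl)) {
      ix <- which(cl == k)
      npg <- npg + 1L
      entries[[length(entries) + 1L]] <- data.table::data.table(
        pgID = sprintf("pg%06d", npg), sog_id = sid,
        ref_chrom = p$ref_chrom[ix[1L]],
        ref_ord = stats::median(p$ref_ord[ix]),
        members = list(p$gene_id[ix]))
    }
  }
  if (!length(entries))
    return(data.table::data.table(pgID = character(), sog_id = character(),
                                  ref_chrom = character(),
                                  ref_ord = numeric(), members = list()))
  data.table::rbindlist(entries)
}

#' Finalize the pan-genome annotation
#'
#' Adds the members the strict positional placement skipped: syntenic
#' orthogroup members without a placed position (flag `indirectSyn`),
#' whole orthogroups with no position at all (entries with NA coordinates),
#' tandem-array members that are not representatives (flag `arrayMember`,
#' next to their representative), and, when a global orthogroup map is
#' supplied, ortholog genes absent from the pan-genome (flag `NSOrtho`).
#' Reference bp positions are taken from the backbone gene nearest to each
#' entry's rank position. Rows with flag `"absent"` mark (entry, genome)
#' cells with no member.
#'
#' @param entries initial entries from [place_orthogroups()].
#' @param sogs syntenic orthogroup table.
#' @param genes combined gene table of the scan.
#' @param ref reference genome name.
#' @param og_map optional global orthogroup map (gene_id -> og) used for the
#'   `NSOrtho` step.
#' @return list with `long` (pgID, sog_id, ref_chrom, ref_ord, ref_bp,
#'   genome, gene_id, flag) and `wide` (one row per entry, comma-joined
#'   member lists per genome).
#' @export
finalize_pangenome <- function(entries, sogs, genes, ref, og_map = NULL) {
  genomes <- sort(unique(sogs$genome))
  sog_of <- stats::setNames(sogs$sog_id, sogs$gene_id)
  genome_of <- stats::setNames(sogs$genome, sogs$gene_id)
  long <- list()
  entry_of_gene <- character(0)
  # entry bookkeeping per sog
  ent <- data.table::copy(entries)
  npg <- if (nrow(ent)) max(as.integer(sub("^pg", "", ent$pgID))) else 0L
  for (i in seq_len(nrow(ent))) {
    mem <- ent$members[[i]]
    long[[length(long) + 1L]] <- data.table::data.table(
      pgID = ent$pgID[i], sog_id = ent$sog_id[i],
      ref_chrom = ent$ref_chrom[i], ref_ord = ent$ref_ord[i],
      genome = unname(genome_of[mem]), gene_id = mem, flag = "synOg")
    entry_of_gene[mem] <- ent$pgID[i]
  }
  # best entry per sog (most direct members, then lower position)
  if (nrow(ent)) {
    ent[, "n_mem" := vapply(ent$members, length, integer(1))]
    bo <- ent[order(ent$sog_id, -ent$n_mem, ent$ref_ord)]
    best_entry <- bo[!duplicated(bo$sog_id)]
    best_of_sog <- stats::setNames(best_entry$pgID, best_entry$sog_id)
    chrom_of_entry <- stats::setNames(ent$ref_chrom, ent$pgID)
    ord_of_entry <- stats::setNames(ent$ref_ord, ent$pgID)
  } else {
    best_of_sog <- character(0)
    chrom_of_entry <- character(0)
    ord_of_entry <- numeric(0)
  }
  sog_entry_lookup <- function(sid) {
    if (sid %in% names(best_of_sog)) best_of_sog[[sid]] else NA_character_
  }
  # position-less sogs -> NA entries; remaining members -> indirectSyn or
  # arrayMember rows
  rep_of_array <- genes[genes$is_array_rep & !is.na(genes$array_id)]
  rep_lookup <- stats::setNames(rep_of_array$gene_id, rep_of_array$array_id)
  gene_tab <- genes[, c("gene_id", "array_id", "is_array_rep")]
  arr_of_gene <- stats::setNames(gene_tab$array_id, gene_tab$gene_id)
  isrep_of_gene <- stats::setNames(gene_tab$is_array_rep, gene_tab$gene_id)
  for (sid in sort(unique(sogs$sog_id))) {
    mem_all <- sogs$gene_id[sogs$sog_id == sid]
    left <- mem_all[!(mem_all %in% names(entry_of_gene))]
    if (!length(left)) next
    target <- sog_entry_lookup(sid)
    if (is.na(target)) {
      npg <- npg + 1L
      target <- sprintf("pg%06d", npg)
      chrom_of_entry[target] <- NA_character_
      ord_of_entry[target] <- NA_real_
      best_of_sog[sid] <- target
    }
    aid <- arr_of_gene[left]
    is_arr_mem <- !is.na(aid) & !isrep_of_gene[left] &
      !is.na(rep_lookup[aid]) &
      rep_lookup[aid] %in% names(entry_of_gene)
    fl <- ifelse(is_arr_mem, "arrayMember",
                 ifelse(is.na(chrom_of_entry[target]), "synOg",
                        "indirectSyn"))
    # array members sit next to their representative's entry
    tgt <- rep(target, length(left))
    tgt[is_arr_mem] <- entry_of_gene[rep_lookup[aid[is_arr_mem]]]
    long[[length(long) + 1L]] <- data.table::data.table(
      pgID = tgt, sog_id = sid,
      ref_chrom = unname(chrom_of_entry[tgt]),
      ref_ord = unname(ord_of_entry[tgt]),
      genome = unname(genome_of[left]), gene_id = left, flag = unname(fl))
    entry_of_gene[left] <- tgt
  }
  long <- data.table::rbindlist(long)
  # non-syntenic orthologs from the global orthogroups
  if (!is.null(og_map)) {
    placed <- unique(long$gene_id)
    cand <- names(og_map)[!(names(og_map) %in% placed)]
    cand <- cand[cand %in% genes$gene_id]
    if (length(cand)) {
      og_entry <- long[, c("gene_id", "pgID", "sog_id", "ref_chrom",
                           "ref_ord")]
      og_entry[, "og" := unname(og_map[og_entry$gene_id])]
      og_entry <- og_entry[!is.na(og_entry$og)]
      og_entry <- og_entry[order(og_entry$pgID)]
      og_first <- og_entry[!duplicated(og_entry$og)]
      m <- match(unname(og_map[cand]), og_first$og)
      ok <- !is.na(m)
      if (any(ok)) {
        gg <- stats::setNames(genes$genome, genes$gene_id)
        long <- data.table::rbindlist(list(long, data.table::data.table(
          pgID = og_first$pgID[m[ok]], sog_id = og_first$sog_id[m[ok]],
          ref_chrom = og_first$ref_chrom[m[ok]],
          ref_ord = og_first$ref_ord[m[ok]],
          genome = unname(gg[cand[ok]]), gene_id = cand[ok],
          flag = "NSOrtho")))
      }
    }
  }
  # absent cells
  pres <- unique(long[, c("pgID", "genome")])
  eg <- data.table::CJ(pgID = unique(long$pgID), genome = genomes)
  miss <- eg[!pres, on = c("pgID", "genome")]
  if (nrow(miss)) {
    einfo <- unique(long[, c("pgID", "sog_id", "ref_chrom", "ref_ord")])
    miss <- merge(miss, einfo, by = "pgID")
    miss[, "gene_id" := NA_character_]
    miss[, "flag" := "absent"]
    long <- data.table::rbindlist(list(long, miss), use.names = TRUE)
  }
  # reference bp from the nearest backbone representative
  backbone <- genes[genes$genome == ref & genes$is_array_rep]
  long[, "ref_bp" := NA_integer_]
  for (ch in unique(stats::na.omit(long$ref_chrom))) {
    bb <- backbone[backbone$chrom == ch]
    ix <- which(!is.na(long$ref_chrom) & long$ref_chrom == ch &
                  !is.na(long$ref_ord))
    if (!nrow(bb) || !length(ix)) next
    # nearest backbone rank
    lo <- pmax(1L, findInterval(long$ref_ord[ix], bb$array_ord))
    hi <- pmin(nrow(bb), lo + 1L)
    pick <- ifelse(abs(bb$array_ord[lo] - long$ref_ord[ix]) <=
                     abs(bb$array_ord[hi] - long$ref_ord[ix]), lo, hi)
    data.table::set(long, ix, "ref_bp", bb$start[pick])
  }
  data.table::setorderv(long, c("ref_chrom", "ref_ord", "pgID", "genome",
                                "gene_id"), na.last = TRUE)
  data.table::setcolorder(long, c("pgID", "sog_id", "ref_chrom", "ref_ord",
                                  "ref_bp", "genome", "gene_id", "flag"))
  # wide format
  real <- long[long$flag != "absent"]
  wide <- data.table::dcast(
    real, pgID + sog_id + ref_chrom + ref_ord ~ genome,
    value.var = "gene_id",
    fun.aggregate = function(x) paste(sort(x), collapse = ","))
  data.table::setorderv(wide, c("ref_chrom", "ref_ord", "pgID"),
                        na.last = TRUE)
  list(long = long[], wide = wide[])
}

#' Presence-absence and copy-number matrices
#'
#' @param pg a `pangenome` object or the long table from
#'   [finalize_pangenome()].
#' @return list with `pav` (logical entry x genome matrix) and `cnv`
#'   (integer member counts; CNV >= 1 exactly where PAV is TRUE).
#' @export
pav_cnv_matrix <- function(pg) {
  long <- if (inherits(pg, "pangenome")) pg$long else pg
  real <- long[long$flag != "absent" & !is.na(long$gene_id)]
  ids <- unique(long$pgID)
  genomes <- sort(unique(long$genome))
  cnv <- matrix(0L, nrow = length(ids), ncol = length(genomes),
                dimnames = list(ids, genomes))
  tab <- real[, list(n = .N), by = c("pgID", "genome")]
  cnv[cbind(match(tab$pgID, ids), match(tab$genome, genomes))] <-
    as.integer(tab$n)
  list(pav = cnv >= 1L, cnv = cnv)
}

#' Build a reference-anchored pan-genome annotation
#'
#' Decodes the pairwise syntenic orthologs of a completed synteny scan into
#' a pan-genome annotation on the chosen reference genome's coordinate
#' system: syntenic orthogroups are aggregated, every array representative
#' in every genome receives an (interpolated) reference rank position,
#' orthogroups are placed at the median position of their positional
#' clusters, and the remaining members are folded in with flags.
#'
#' @param scan `synteny_scan` object from [run_synteny()].
#' @param ref reference genome name (must be part of the scan).
#' @param og_map optional global orthogroup map for the non-syntenic
#'   ortholog (NSOrtho) step.
#' @return object of class `pangenome`: list(ref, long, wide, pav, cnv,
#'   sogs, entries).
#' @export
build_pangenome <- function(scan, ref, og_map = NULL) {
  stopifnot(inherits(scan, "synteny_scan"))
  if (!(ref %in% names(scan$genomes)))
    stop("reference genome '", ref, "' is not part of the scan")
  sogs <- syntenic_orthogroups(scan)
  positions <- gene_ref_positions(scan, ref)
  entries <- place_orthogroups(sogs, positions, scan$params)
  fin <- finalize_pangenome(entries, sogs, scan$genes, ref, og_map)
  mats <- pav_cnv_matrix(fin$long)
  structure(list(ref = ref, long = fin$long, wide = fin$wide,
                 pav = mats$pav, cnv = mats$cnv, sogs = sogs,
                 entries = entries),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat("Pan-genome annotation on reference '", x$ref, "'\n", sep = "")
  cat("  entries:", length(unique(x$long$pgID)),
      " genomes:", ncol(x$pav), "\n")
  core <- sum(rowSums(x$pav) == ncol(x$pav))
  cat(sprintf("  core entries (present in all genomes): %d (%.1f%%)\n",
              core, 100 * core / nrow(x$pav)))
  invisible(x)
}

#' @export
summary.pangenome <- function(object, ...) {
  pav <- object$pav
  out <- list(
    n_entries = nrow(pav),
    n_genomes = ncol(pav),
    core = sum(rowSums(pav) == ncol(pav)),
    dispensable = sum(rowSums(pav) < ncol(pav) & rowSums(pav) > 0L),
    per_genome_genes = colSums(object$cnv))
  class(out) <- "summary.pangenome"
  out
}

#' @export
print.summary.pangenome <- function(x, ...) {
  cat("Pan-genome:", x$n_entries, "entries across", x$n_genomes,
      "genomes\n")
  cat("  core:", x$core, " dispensable:", x$dispensable, "\n")
  cat("  genes per genome:\n")
  print(x$per_genome_genes)
  invisible(x)
}
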