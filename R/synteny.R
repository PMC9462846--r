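#' Decorate raw hits with positional, array, orthogroup and score-rank data
#'
#' Attaches to every hit: chromosome and gene rank order of both genes,
#' condensed array rank (rank among tandem-array representatives), array
#' representative flags, a shared-orthogroup flag (`isOg`), and the relative
#' strength of the hit (`scrRankQ`/`scrRankT`: dense rank of bitscore among
#' all hits sharing the query/target gene; 1 = best, equal bitscores share
#' a rank). Hits whose genes were QC-dropped are silently excluded (the
#' count is attached as attribute `"n_excluded"`).
#'
#' @param hits raw hit table from [read_hits()].
#' @param genesQ,genesT gene tables after [find_tandem_arrays()].
#' @return annotated hit `data.table`.
#' @export
annotate_hits <- function(hits, genesQ, genesT) {
  bitscore <- NULL
  iq <- match(hits$query, genesQ$gene_id)
  it <- match(hits$target, genesT$gene_id)
  keep <- !is.na(iq) & !is.na(it)
  h <- hits[keep]
  iq <- iq[keep]; it <- it[keep]
  h[, "chromQ" := genesQ$chrom[iq]]
  h[, "chromT" := genesT$chrom[it]]
  h[, "ordQ" := genesQ$ord[iq]]
  h[, "ordT" := genesT$ord[it]]
  h[, "arrayOrdQ" := genesQ$array_ord[iq]]
  h[, "arrayOrdT" := genesT$array_ord[it]]
  h[, "repQ" := genesQ$is_array_rep[iq]]
  h[, "repT" := genesT$is_array_rep[it]]
  h[, "bpQs" := genesQ$start[iq]]
  h[, "bpQe" := genesQ$end[iq]]
  h[, "bpTs" := genesT$start[it]]
  h[, "bpTe" := genesT$end[it]]
  ogq <- genesQ$og[iq]; ogt <- genesT$og[it]
  h[, "isOg" := !is.na(ogq) & !is.na(ogt) & ogq == ogt]
  data.table::setorderv(h, c("chromQ", "chromT", "ordQ", "ordT"))
  h[, "scrRankQ" := data.table::frank(-bitscore, ties.method = "dense"),
    by = "query"]
  h[, "scrRankT" := data.table::frank(-bitscore, ties.method = "dense"),
    by = "target"]
  h[, "isPotential" := FALSE]
  h[, "xc" := NA_integer_]
  h[, "yc" := NA_integer_]
  h[, "isAnchor" := FALSE]
  h[, "inBuffer" := FALSE]
  h[, "blk_id" := NA_character_]
  h[, "reg_id" := NA_character_]
  h[, "orientation" := NA_character_]
  data.table::setattr(h, "genomeQ", attr(hits, "genomeQ", exact = TRUE))
  data.table::setattr(h, "genomeT", attr(hits, "genomeT", exact = TRUE))
  data.table::setattr(h, "n_excluded", sum(!keep))
  h[]
}

#' Flag potential syntenic anchors
#'
#' A hit is a potential anchor when both genes are tandem-array
#' representatives, the hit is not masked, its score rank is within the
#' top-n cutoffs on both sides, and (if `onlyOg`) both genes share an
#' orthogroup. Score ranks are recomputed on the unmasked hits so that
#' masked scans (polyploid self synteny, secondary-hit scans) rank the
#' remaining candidates properly. Condensed rank-order positions (`xc`,
#' `yc`) are recomputed on the flagged subset per chromosome pair; all
#' chaining runs on these condensed positions.
#'
#' @param hits annotated hit table.
#' @param nHits1,nHits2 integer top-n cutoffs (already resolved).
#' @param onlyOg require shared orthogroup?
#' @param mask logical vector (TRUE = hit masked out of the scan), or NULL.
#' @return the hit table with `isPotential`, `xc`, `yc` updated.
#' @export
flag_potential_anchors <- function(hits, nHits1, nHits2, onlyOg = TRUE,
                                   mask = NULL) {
  bitscore <- arrayOrdQ <- arrayOrdT <- NULL
  h <- data.table::copy(hits)
  if (is.null(mask)) mask <- rep(FALSE, nrow(h))
  h[, "scrRankQ" := NA_integer_]
  h[, "scrRankT" := NA_integer_]
  h[!mask, "scrRankQ" := data.table::frank(-bitscore, ties.method = "dense"),
    by = "query"]
  h[!mask, "scrRankT" := data.table::frank(-bitscore, ties.method = "dense"),
    by = "target"]
  pot <- !mask & h$repQ & h$repT &
    !is.na(h$scrRankQ) & h$scrRankQ <= nHits1 & h$scrRankT <= nHits2
  if (onlyOg) pot <- pot & h$isOg
  h[, "isPotential" := pot]
  h[, "xc" := NA_integer_]
  h[, "yc" := NA_integer_]
  h[pot, "xc" := as.integer(data.table::frank(arrayOrdQ,
                                              ties.method = "dense")),
    by = c("chromQ", "chromT")]
  h[pot, "yc" := as.integer(data.table::frank(arrayOrdT,
                                              ties.method = "dense")),
    by = c("chromQ", "chromT")]
  h[]
}

#' Flag initial syntenic anchors by collinear chaining
#'
#' Runs [chain_collinear()] on the potential anchors of every chromosome
#' pair; members of retained chains (>= blkSize hits, gaps <= nGaps) are
#' flagged `isAnchor`.
#'
#' @param hits hit table after [flag_potential_anchors()].
#' @param blkSize,nGaps chaining parameters.
#' @return the hit table with `isAnchor` and `orientation` set.
#' @export
define_initial_anchors <- function(hits, blkSize, nGaps) {
  h <- data.table::copy(hits)
  h[, "isAnchor" := FALSE]
  h[, "orientation" := NA_character_]
  pot <- which(h$isPotential)
  if (!length(pot)) return(h[])
  cp <- split(pot, paste(h$chromQ[pot], h$chromT[pot], sep = "\r"))
  for (rows in cp) {
    if (length(rows) < blkSize) next
    chains <- chain_collinear(h$xc[rows], h$yc[rows], blkSize, nGaps)
    for (ch in chains) {
      data.table::set(h, rows[ch$idx], "isAnchor", TRUE)
      data.table::set(h, rows[ch$idx], "orientation", ch$orientation)
    }
  }
  h[]
}

# Minimum Chebyshev distance from each point to a set of anchor points,
# chunked so the distance matrix never gets large. Returns +Inf where the
# anchor set is empty. `which` additionally returns the index (into the
# anchor vectors) of the nearest anchor, first-in-order on ties.
cheb_nearest <- function(px, py, ax, ay, chunk = 512L) {
  n <- length(px)
  d <- rep(Inf, n)
  w <- rep(NA_integer_, n)
  if (!length(ax) || !n) return(list(dist = d, which = w))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- abs(outer(px[s:e], ax, "-"))
    dy <- abs(outer(py[s:e], ay, "-"))
    dm <- pmax(dx, dy)
    wi <- max.col(-dm, ties.method = "first")
    d[s:e] <- dm[cbind(seq_len(e - s + 1L), wi)]
    w[s:e] <- wi
  }
  list(dist = d, which = w)
}

#' Refine initial anchors into syntenic blocks
#'
#' Implements the block-finalization cascade: (1) potential anchors within
#' a Chebyshev radius of `synBuff` (array-rank space) of any initial anchor
#' are re-chained into cleaned anchors; (2) cleaned anchors are clustered
#' into regions by DBSCAN (Euclidean, eps = synBuff, minPts = blkSize),
#' dropping clusters smaller than blkSize; (3) chaining is rerun within each
#' region, giving the final anchors; (4) a fine DBSCAN (eps = blkSize) on
#' re-ranked anchor positions splits a chain into sub-blocks only when every
#' piece still holds >= blkSize anchors; (5) where two non-duplicated blocks
#' overlap on both axes, anchors in the overlap go to the block with the
#' longest consecutive run there (run-length reassignment), and losers
#' reduced below blkSize are absorbed entirely.
#'
#' @param hits hit table after [define_initial_anchors()].
#' @param params [synteny_params()].
#' @param blkSize,nGaps,synBuff scan-specific overrides of `params`.
#' @param blk_prefix prefix for generated block ids.
#' @return list with `hits` (blk_id, isAnchor, orientation updated) and
#'   `blocks` (one row per block; coordinates filled by [finalize_hits()]).
#' @export
refine_blocks <- function(hits, params, blkSize = params$blkSize,
                          nGaps = params$nGaps, synBuff = params$synBuff,
                          blk_prefix = "blk") {
  h <- data.table::copy(hits)
  h[, "blk_id" := NA_character_]
  blocks <- list()
  pot <- which(h$isPotential)
  init <- which(h$isAnchor)
  h[, "isAnchor" := FALSE]
  h[, "orientation" := NA_character_]
  if (!length(init)) return(list(hits = h[], blocks = empty_block_table()))
  cp <- split(seq_len(nrow(h)),
              paste(h$chromQ, h$chromT, sep = "\r"))
  nblk <- 0L
  for (rows in cp) {
    A <- intersect(rows, init)
    if (!length(A)) next
    P <- intersect(rows, pot)
    near <- cheb_nearest(h$arrayOrdQ[P], h$arrayOrdT[P],
                         h$arrayOrdQ[A], h$arrayOrdT[A])
    S <- P[near$dist <= synBuff]
    if (length(S) < blkSize) next
    # (1) re-chain the buffered potential anchors on the pair-level
    # condensed ranks (re-condensing on the sparse subset would let chains
    # bridge arbitrarily large real gaps)
    chains1 <- chain_collinear(h$xc[S], h$yc[S], blkSize, nGaps)
    C <- S[sort(unlist(lapply(chains1, `[[`, "idx")))]
    if (length(C) < blkSize) next
    # (2) DBSCAN into regions
    lab <- dbscan_xy(h$arrayOrdQ[C], h$arrayOrdT[C], eps = synBuff,
                     minPts = blkSize)
    for (rg in setdiff(sort(unique(lab)), 0L)) {
      R <- C[lab == rg]
      if (length(R) < blkSize) next
      # (3) final chaining within the region, same coordinate system
      chains <- chain_collinear(h$xc[R], h$yc[R], blkSize, nGaps)
      if (!length(chains)) next
      anchors <- R[sort(unlist(lapply(chains, `[[`, "idx")))]
      # (4) fine breakpoint clustering on re-ranked anchor positions
      fx <- as.integer(data.table::frank(h$arrayOrdQ[anchors],
                                         ties.method = "dense"))
      fy <- as.integer(data.table::frank(h$arrayOrdT[anchors],
                                         ties.method = "dense"))
      fine <- dbscan_xy(fx, fy, eps = blkSize, minPts = 1L)
      blk_members <- list()
      blk_orient <- character(0)
      for (ch in chains) {
        mem <- R[ch$idx]
        fl <- fine[match(mem, anchors)]
        pieces <- split(mem, fl)
        if (length(pieces) > 1L &&
            all(vapply(pieces, length, integer(1)) >= blkSize)) {
          for (pc in pieces) {
            blk_members[[length(blk_members) + 1L]] <- pc
            blk_orient <- c(blk_orient, ch$orientation)
          }
        } else {
          blk_members[[length(blk_members) + 1L]] <- mem
          blk_orient <- c(blk_orient, ch$orientation)
        }
      }
      ov <- resolve_block_overlaps(h, blk_members, blkSize)
      blk_members <- ov$members
      blk_orient <- blk_orient[ov$keep]
      for (bi in seq_along(blk_members)) {
        mem <- blk_members[[bi]]
        if (!length(mem)) next
        nblk <- nblk + 1L
        bid <- sprintf("%s_%05d", blk_prefix, nblk)
        data.table::set(h, mem, "isAnchor", TRUE)
        data.table::set(h, mem, "blk_id", bid)
        data.table::set(h, mem, "orientation", blk_orient[bi])
        blocks[[length(blocks) + 1L]] <- data.table::data.table(
          blk_id = bid, reg_id = NA_character_,
          genomeQ = attr(h, "genomeQ", exact = TRUE) %||% NA_character_,
          genomeT = attr(h, "genomeT", exact = TRUE) %||% NA_character_,
          chromQ = h$chromQ[mem[1L]], chromT = h$chromT[mem[1L]],
          orientation = blk_orient[bi], n_anchors = length(mem),
          minAoQ = NA_integer_, maxAoQ = NA_integer_,
          minAoT = NA_integer_, maxAoT = NA_integer_,
          startQ = NA_integer_, endQ = NA_integer_,
          startT = NA_integer_, endT = NA_integer_,
          is_secondary = FALSE, is_self = FALSE)
      }
    }
  }
  blocks <- if (length(blocks)) data.table::rbindlist(blocks)
  else empty_block_table()
  list(hits = h[], blocks = blocks[])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_block_table <- function() {
  data.table::data.table(
    blk_id = character(), reg_id = character(), genomeQ = character(),
    genomeT = character(), chromQ = character(), chromT = character(),
    orientation = character(), n_anchors = integer(),
    minAoQ = integer(), maxAoQ = integer(), minAoT = integer(),
    maxAoT = integer(), startQ = integer(), endQ = integer(),
    startT = integer(), endT = integer(), is_secondary = logical(),
    is_self = logical())
}

# Run-length reassignment of anchors in the overlap of two non-duplicated
# blocks: among the overlap anchors sorted along the query axis, the block
# holding the longest consecutive run keeps them; a loser left with fewer
# than blkSize anchors is absorbed entirely into the winner.
resolve_block_overlaps <- function(h, members, blkSize) {
  nb <- length(members)
  if (nb < 2L) return(list(members = members, keep = seq_len(nb)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    nb <- length(members)
    for (i in seq_len(nb - 1L)) {
      for (j in (i + 1L):nb) {
        mi <- members[[i]]; mj <- members[[j]]
        if (!length(mi) || !length(mj)) next
        qi <- range(h$arrayOrdQ[mi]); qj <- range(h$arrayOrdQ[mj])
        ti <- range(h$arrayOrdT[mi]); tj <- range(h$arrayOrdT[mj])
        qov <- c(max(qi[1L], qj[1L]), min(qi[2L], qj[2L]))
        tov <- c(max(ti[1L], tj[1L]), min(ti[2L], tj[2L]))
        # duplicated placements (overlap on one axis only) are left alone
        if (qov[1L] > qov[2L] || tov[1L] > tov[2L]) next
        comb <- c(mi, mj)
        lab <- c(rep(i, length(mi)), rep(j, length(mj)))
        o <- order(h$arrayOrdQ[comb], h$arrayOrdT[comb])
        comb <- comb[o]; lab <- lab[o]
        inov <- h$arrayOrdQ[comb] >= qov[1L] & h$arrayOrdQ[comb] <= qov[2L]
        if (!any(inov)) next
        r <- rle(lab[inov])
        win <- r$values[which.max(r$lengths)]
        lose <- if (win == i) j else i
        moved <- comb[inov & lab == lose]
        if (!length(moved)) next
        members[[win]] <- sort(c(members[[win]], moved))
        members[[lose]] <- setdiff(members[[lose]], moved)
        if (length(members[[lose]]) < blkSize) {
          members[[win]] <- sort(c(members[[win]], members[[lose]]))
          members[[lose]] <- integer(0)
        }
        changed <- TRUE
      }
    }
    if (changed) next
  }
  keep <- which(vapply(members, length, integer(1)) > 0L)
  list(members = members[keep], keep = keep)
}

#' Assign regions, the syntenic buffer, and block coordinates
#'
#' Final anchors are re-clustered per chromosome pair by DBSCAN with radius
#' `synBuff` (minPts 1) and each cluster becomes a region (`reg_id`). Every
#' hit — anchor or not — within Chebyshev radius `synBuff` of an anchor is
#' flagged `inBuffer` and inherits the nearest anchor's region (ties go to
#' the lower `reg_id`). Block and region bp coordinates are the extrema of
#' their bounding anchor genes.
#'
#' @param hits hit table after [refine_blocks()].
#' @param blocks block table from [refine_blocks()].
#' @param synBuff buffer radius (array-rank units).
#' @param reg_prefix prefix for generated region ids.
#' @return list(hits, blocks) with reg_id, inBuffer and coordinates filled.
#' @export
finalize_hits <- function(hits, blocks, synBuff, reg_prefix = "reg") {
  h <- data.table::copy(hits)
  blocks <- data.table::copy(blocks)
  h[, "reg_id" := NA_character_]
  h[, "inBuffer" := FALSE]
  anc <- which(h$isAnchor)
  if (!length(anc)) return(list(hits = h[], blocks = blocks))
  cp <- split(seq_len(nrow(h)), paste(h$chromQ, h$chromT, sep = "\r"))
  nreg <- 0L
  for (rows in cp) {
    A <- intersect(rows, anc)
    if (!length(A)) next
    lab <- dbscan_xy(h$arrayOrdQ[A], h$arrayOrdT[A], eps = synBuff,
                     minPts = 1L)
    regs <- sort(unique(lab))
    rid <- stats::setNames(sprintf("%s_%05d", reg_prefix, nreg + seq_along(regs)),
                           regs)
    nreg <- nreg + length(regs)
    data.table::set(h, A, "reg_id", unname(rid[as.character(lab)]))
    # anchors sorted by (region, position): nearest-anchor ties resolve to
    # the lower reg_id via first-minimum selection
    o <- order(rid[as.character(lab)], h$arrayOrdQ[A], h$arrayOrdT[A])
    As <- A[o]
    near <- cheb_nearest(h$arrayOrdQ[rows], h$arrayOrdT[rows],
                         h$arrayOrdQ[As], h$arrayOrdT[As])
    inb <- near$dist <= synBuff
    data.table::set(h, rows[inb], "inBuffer", TRUE)
    data.table::set(h, rows[inb], "reg_id", h$reg_id[As][near$which[inb]])
  }
  # block coordinates + region inheritance from member anchors
  if (nrow(blocks)) {
    for (bi in seq_len(nrow(blocks))) {
      mem <- which(!is.na(h$blk_id) & h$blk_id == blocks$blk_id[bi])
      if (!length(mem)) next
      data.table::set(blocks, bi, "reg_id", h$reg_id[mem[1L]])
      data.table::set(blocks, bi, "minAoQ", min(h$arrayOrdQ[mem]))
      data.table::set(blocks, bi, "maxAoQ", max(h$arrayOrdQ[mem]))
      data.table::set(blocks, bi, "minAoT", min(h$arrayOrdT[mem]))
      data.table::set(blocks, bi, "maxAoT", max(h$arrayOrdT[mem]))
      data.table::set(blocks, bi, "startQ", min(h$bpQs[mem]))
      data.table::set(blocks, bi, "endQ", max(h$bpQe[mem]))
      data.table::set(blocks, bi, "startT", min(h$bpTs[mem]))
      data.table::set(blocks, bi, "endT", max(h$bpTe[mem]))
    }
  }
  list(hits = h[], blocks = blocks[])
}

#' Run the full anchor-to-block cascade for one genome pair
#'
#' Convenience wrapper chaining [flag_potential_anchors()],
#' [define_initial_anchors()], [refine_blocks()] and [finalize_hits()] with
#' one parameter set. Used directly by the primary scan and reused (with
#' masks and alternative parameters) by the polyploid self scan and the
#' secondary-hit scan.
#'
#' @param hits annotated hit table ([annotate_hits()]).
#' @param params [synteny_params()].
#' @param genomeQ,genomeT genome names (for nHits resolution and ids).
#' @param mask logical mask of hits excluded from anchor candidacy.
#' @param blkSize,nGaps,synBuff scan parameters.
#' @param nHits1,nHits2 top-n cutoffs; NULL resolves from ploidy.
#' @param onlyOg require shared orthogroups for anchors.
#' @param blk_prefix,reg_prefix id prefixes.
#' @param is_secondary,is_self labels stamped on the resulting blocks.
#' @return list(hits, blocks).
#' @export
synteny_pair <- function(hits, params, genomeQ, genomeT, mask = NULL,
                         blkSize = params$blkSize, nGaps = params$nGaps,
                         synBuff = params$synBuff, nHits1 = NULL,
                         nHits2 = NULL, onlyOg = params$onlyOgAnchors,
                         blk_prefix = NULL, reg_prefix = NULL,
                         is_secondary = FALSE, is_self = FALSE) {
  if (is.null(nHits1) || is.null(nHits2)) {
    nh <- resolve_nhits(params, genomeQ, genomeT)
    if (is.null(nHits1)) nHits1 <- nh[["nHits1"]]
    if (is.null(nHits2)) nHits2 <- nh[["nHits2"]]
  }
  tag <- paste0(genomeQ, "_vs_", genomeT, if (is_secondary) "_2nd" else "")
  if (is.null(blk_prefix)) blk_prefix <- paste0("blk_", tag)
  if (is.null(reg_prefix)) reg_prefix <- paste0("reg_", tag)
  h <- flag_potential_anchors(hits, nHits1, nHits2, onlyOg, mask)
  h <- define_initial_anchors(h, blkSize, nGaps)
  rb <- refine_blocks(h, params, blkSize, nGaps, synBuff, blk_prefix)
  fin <- finalize_hits(rb$hits, rb$blocks, synBuff, reg_prefix)
  if (nrow(fin$blocks)) {
    data.table::set(fin$blocks, j = "is_secondary",
                    value = rep(is_secondary, nrow(fin$blocks)))
    data.table::set(fin$blocks, j = "is_self",
                    value = rep(is_self, nrow(fin$blocks)))
  }
  fin
}

#' Self-synteny of one genome
#'
#' Haploid genomes yield one identity block per chromosome (anchors are the
#' self hits of the tandem-array representatives; block and region ids are
#' the chromosome ids). For ploidy p > 1 the identity diagonal plus a
#' `selfMaskRadius` neighborhood is masked and the standard cascade is rerun
#' with nHits = p - 1 to recover homeologous blocks.
#'
#' @param genes gene table of the genome (after tandem detection).
#' @param params [synteny_params()].
#' @param hits intragenomic annotated hit table; required when ploidy > 1.
#' @return list(hits (or NULL for haploid), blocks).
#' @export
self_synteny <- function(genes, params, hits = NULL) {
  gname <- genes$genome[1L]
  p <- ploidy_of(params, gname)
  if (p < 1L) stop("ploidy must be >= 1 for genome ", gname)
  reps <- genes[genes$is_array_rep]
  ident <- reps[, list(
    n_anchors = .N,
    minAo = min(array_ord), maxAo = max(array_ord),
    start = min(start), end = max(end)), by = "chrom"]
  data.table::setorderv(ident, "chrom")
  identity_blocks <- data.table::data.table(
    blk_id = ident$chrom, reg_id = ident$chrom,
    genomeQ = gname, genomeT = gname,
    chromQ = ident$chrom, chromT = ident$chrom,
    orientation = "+", n_anchors = ident$n_anchors,
    minAoQ = ident$minAo, maxAoQ = ident$maxAo,
    minAoT = ident$minAo, maxAoT = ident$maxAo,
    startQ = ident$start, endQ = ident$end,
    startT = ident$start, endT = ident$end,
    is_secondary = FALSE, is_self = TRUE)
  if (p == 1L) return(list(hits = hits, blocks = identity_blocks))
  if (is.null(hits))
    stop("intragenomic hits are required for self-synteny at ploidy > 1")
  mask <- hits$chromQ == hits$chromT &
    abs(hits$arrayOrdQ - hits$arrayOrdT) <= params$selfMaskRadius
  mask[is.na(mask)] <- TRUE
  res <- synteny_pair(hits, params, gname, gname, mask = mask,
                      nHits1 = p - 1L, nHits2 = p - 1L,
                      blk_prefix = paste0("blk_", gname, "_self"),
                      reg_prefix = paste0("reg_", gname, "_self"),
                      is_self = TRUE)
  res$blocks <- data.table::rbindlist(list(identity_blocks, res$blocks))
  res
}

#' Secondary (paralog) synteny scan
#'
#' Masks every hit within `synBuff` (Chebyshev, array-rank space) of a
#' primary anchor, then reruns the cascade with the "Second" parameter set,
#' `nHits = nSecondaryHits`, and no orthogroup requirement. Used to recover
#' whole-genome-duplication paralogous regions that the orthogroup-
#' constrained primary scan deliberately skips.
#'
#' @param primary list(hits, blocks) from the primary [synteny_pair()] run.
#' @param params [synteny_params()] with `nSecondaryHits > 0`.
#' @param genomeQ,genomeT genome names.
#' @return list(hits, blocks) of the secondary scan (blocks flagged
#'   `is_secondary`), or NULL when `nSecondaryHits == 0`.
#' @export
secondary_hits_scan <- function(primary, params, genomeQ, genomeT) {
  if (params$nSecondaryHits < 1L) return(NULL)
  h <- data.table::copy(primary$hits)
  anc <- which(h$isAnchor)
  mask <- rep(FALSE, nrow(h))
  if (length(anc)) {
    cp <- split(seq_len(nrow(h)), paste(h$chromQ, h$chromT, sep = "\r"))
    for (rows in cp) {
      A <- intersect(rows, anc)
      if (!length(A)) next
      near <- cheb_nearest(h$arrayOrdQ[rows], h$arrayOrdT[rows],
                           h$arrayOrdQ[A], h$arrayOrdT[A])
      mask[rows[near$dist <= params$synBuff]] <- TRUE
    }
  }
  synteny_pair(h, params, genomeQ, genomeT, mask = mask,
               blkSize = params$blkSizeSecond, nGaps = params$nGapsSecond,
               synBuff = params$synBuffSecond,
               nHits1 = params$nSecondaryHits,
               nHits2 = params$nSecondaryHits,
               onlyOg = FALSE, is_secondary = TRUE)
}
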