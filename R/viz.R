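#' Dotplot coordinates for one genome pair
#'
#' One row per in-buffer hit, at condensed (array) rank positions, with the
#' block id and a deterministic color key (blocks numbered in order of
#' appearance along the query axis).
#'
#' @param pair a pair result (`list(hits, blocks)`) from a scan.
#' @return `data.table` with x, y, chromQ, chromT, blk_id, reg_id,
#'   isAnchor, color_key.
#' @export
dotplot_table <- function(pair) {
  h <- pair$hits
  hb <- h[h$inBuffer]
  if (!nrow(hb))
    return(data.table::data.table(
      x = integer(), y = integer(), chromQ = character(),
      chromT = character(), blk_id = character(), reg_id = character(),
      isAnchor = logical(), color_key = integer()))
  out <- data.table::data.table(
    x = hb$arrayOrdQ, y = hb$arrayOrdT, chromQ = hb$chromQ,
    chromT = hb$chromT, blk_id = hb$blk_id, reg_id = hb$reg_id,
    isAnchor = hb$isAnchor)
  data.table::setorderv(out, c("chromQ", "chromT", "x", "y"))
  blks <- unique(stats::na.omit(out$blk_id))
  key <- stats::setNames(seq_along(blks), blks)
  out[, "color_key" := ifelse(is.na(out$blk_id), 0L,
                              unname(key[out$blk_id]))]
  out[]
}

#' Order chromosomes to maximize synteny with a reference
#'
#' Reference chromosomes keep their natural (sorted) order; every other
#' genome's chromosomes are ordered by the anchor-count-weighted mean
#' reference position of their blocks. Chromosomes without blocks sort
#' last, by name.
#'
#' @param blocks block table ([scan_blocks()] or a pair's blocks).
#' @param ref reference genome name.
#' @return named list: per genome, the ordered chromosome vector.
#' @export
order_chromosomes <- function(blocks, ref) {
  b <- blocks[!blocks$is_self & !blocks$is_secondary]
  genomes <- sort(unique(c(b$genomeQ, b$genomeT)))
  out <- list()
  refchr <- sort(unique(c(b$chromQ[b$genomeQ == ref],
                          b$chromT[b$genomeT == ref])))
  out[[ref]] <- refchr
  refpos <- stats::setNames(seq_along(refchr), refchr)
  for (g in setdiff(genomes, ref)) {
    # blocks joining g to ref, in either orientation
    b1 <- b[b$genomeQ == g & b$genomeT == ref]
    b2 <- b[b$genomeT == g & b$genomeQ == ref]
    tab <- data.table::rbindlist(list(
      data.table::data.table(chrom = b1$chromQ,
                             refchrom = b1$chromT,
                             refmid = (b1$minAoT + b1$maxAoT) / 2,
                             w = b1$n_anchors),
      data.table::data.table(chrom = b2$chromT,
                             refchrom = b2$chromQ,
                             refmid = (b2$minAoQ + b2$maxAoQ) / 2,
                             w = b2$n_anchors)))
    allchr <- sort(unique(c(b$chromQ[b$genomeQ == g],
                            b$chromT[b$genomeT == g])))
    if (nrow(tab)) {
      tab[, "gpos" := unname(refpos[tab$refchrom]) * 1e9 + tab$refmid]
      sc <- tab[, list(pos = sum(gpos * w) / sum(w)), by = "chrom"]
      scored <- sc$chrom[order(sc$pos, sc$chrom)]
      out[[g]] <- c(scored, setdiff(allchr, scored))
    } else {
      out[[g]] <- allchr
    }
  }
  out
}

#' Riparian (braided ribbon) layout coordinates
#'
#' Computes, for a user-supplied vertical order of genomes, the horizontal
#' chromosome segments of each genome row (widths proportional to gene
#' counts) and one braid polygon per syntenic region connecting each pair
#' of vertically adjacent genomes. Optional highlight chromosomes on the
#' top genome propagate transitively down the rows through the regions they
#' touch.
#'
#' @param scan `synteny_scan` object.
#' @param genome_order character vector, top row first.
#' @param ref reference genome used for chromosome ordering (defaults to
#'   the first of `genome_order`).
#' @param highlight character vector of chromosomes of the top genome to
#'   track.
#' @return object of class `riparian_layout`: list(segments, braids,
#'   highlight).
#' @export
riparian_layout <- function(scan, genome_order = names(scan$genomes),
                            ref = genome_order[1L], highlight = NULL) {
  blocks <- scan_blocks(scan, include_self = FALSE,
                        include_secondary = FALSE)
  chrord <- order_chromosomes(blocks, ref)
  gap <- 0.02
  segments <- list()
  for (gi in seq_along(genome_order)) {
    g <- genome_order[gi]
    genes <- scan$genomes[[g]]
    chrs <- chrord[[g]] %||% sort(unique(genes$chrom))
    chrs <- c(chrs, setdiff(sort(unique(genes$chrom)), chrs))
    sizes <- vapply(chrs, function(ch) sum(genes$chrom == ch), numeric(1))
    tot <- sum(sizes) + gap * (length(chrs) - 1L) * sum(sizes)
    w <- sizes / tot
    x0 <- cumsum(c(0, head(w, -1L) + gap * sum(sizes) / tot))
    segments[[g]] <- data.table::data.table(
      genome = g, chrom = chrs, x0 = x0, x1 = x0 + w,
      y = length(genome_order) - gi, n_genes = sizes)
  }
  seg <- data.table::rbindlist(segments)
  # per-genome scale: chromosome rank position -> plot x
  chr_x <- function(g, ch, ao) {
    s <- seg[seg$genome == g & seg$chrom == ch]
    if (!nrow(s)) return(rep(NA_real_, length(ao)))
    ng <- max(1L, s$n_genes)
    s$x0 + (pmin(ao, ng) - 1) / max(1L, ng - 1L) * (s$x1 - s$x0)
  }
  braids <- list()
  for (gi in seq_len(length(genome_order) - 1L)) {
    gtop <- genome_order[gi]; gbot <- genome_order[gi + 1L]
    b1 <- blocks[blocks$genomeQ == gtop & blocks$genomeT == gbot]
    b2 <- blocks[blocks$genomeQ == gbot & blocks$genomeT == gtop]
    bb <- data.table::rbindlist(list(
      data.table::data.table(reg_id = b1$reg_id, chromTop = b1$chromQ,
                             aoTop0 = b1$minAoQ, aoTop1 = b1$maxAoQ,
                             chromBot = b1$chromT, aoBot0 = b1$minAoT,
                             aoBot1 = b1$maxAoT, n_anchors = b1$n_anchors),
      data.table::data.table(reg_id = b2$reg_id, chromTop = b2$chromT,
                             aoTop0 = b2$minAoT, aoTop1 = b2$maxAoT,
                             chromBot = b2$chromQ, aoBot0 = b2$minAoQ,
                             aoBot1 = b2$maxAoQ, n_anchors = b2$n_anchors)))
    if (!nrow(bb)) {
      warning("no blocks between adjacent genomes ", gtop, " and ", gbot)
      next
    }
    # merge blocks into their regions
    rg <- bb[, list(chromTop = chromTop[1L], aoTop0 = min(aoTop0),
                    aoTop1 = max(aoTop1), chromBot = chromBot[1L],
                    aoBot0 = min(aoBot0), aoBot1 = max(aoBot1),
                    n_anchors = sum(n_anchors)), by = "reg_id"]
    rg[, "topGenome" := gtop]
    rg[, "botGenome" := gbot]
    rg[, "xTop0" := mapply(function(ch, ao) chr_x(gtop, ch, ao),
                           rg$chromTop, rg$aoTop0)]
    rg[, "xTop1" := mapply(function(ch, ao) chr_x(gtop, ch, ao),
                           rg$chromTop, rg$aoTop1)]
    rg[, "xBot0" := mapply(function(ch, ao) chr_x(gbot, ch, ao),
                           rg$chromBot, rg$aoBot0)]
    rg[, "xBot1" := mapply(function(ch, ao) chr_x(gbot, ch, ao),
                           rg$chromBot, rg$aoBot1)]
    rg[, "yTop" := length(genome_order) - gi]
    rg[, "yBot" := length(genome_order) - gi - 1L]
    braids[[length(braids) + 1L]] <- rg
  }
  braids <- if (length(braids)) data.table::rbindlist(braids)
  else data.table::data.table()
  # propagate highlights down the rows through touched regions
  hl <- list()
  if (!is.null(highlight) && nrow(braids)) {
    cur <- data.table::data.table(genome = genome_order[1L],
                                  chrom = highlight)
    hl[[1L]] <- cur
    for (gi in seq_len(length(genome_order) - 1L)) {
      gtop <- genome_order[gi]
      sel <- braids[braids$topGenome == gtop &
                      paste(braids$topGenome, braids$chromTop) %in%
                      paste(cur$genome, cur$chrom)]
      if (!nrow(sel)) break
      cur <- unique(data.table::data.table(
        genome = genome_order[gi + 1L], chrom = sel$chromBot))
      hl[[length(hl) + 1L]] <- cur
    }
  }
  hl <- if (length(hl)) data.table::rbindlist(hl)
  else data.table::data.table(genome = character(), chrom = character())
  structure(list(segments = seg, braids = braids, highlight = hl),
            class = "riparian_layout")
}

#' @export
plot.synteny_scan <- function(x, pair = names(x$pairs)[1L], ...) {
  pr <- x$pairs[[pair]]
  if (is.null(pr)) stop("no such pair: ", pair)
  dt <- dotplot_table(pr)
  if (!nrow(dt)) {
    graphics::plot.new()
    graphics::title(main = paste0("No syntenic hits: ", pair))
    return(invisible(NULL))
  }
  fq <- factor(dt$chromQ); ft <- factor(dt$chromT)
  offq <- c(0, cumsum(tapply(dt$x, fq, max)))
  offt <- c(0, cumsum(tapply(dt$y, ft, max)))
  px <- dt$x + offq[as.integer(fq)]
  py <- dt$y + offt[as.integer(ft)]
  graphics::plot(px, py, pch = 16, cex = 0.3,
                 col = ifelse(dt$color_key == 0L, "grey70",
                              grDevices::hcl.colors(
                                max(dt$color_key), "Dark 3")[dt$color_key]),
                 xlab = paste(attr(pr$hits, "genomeQ"), "gene rank"),
                 ylab = paste(attr(pr$hits, "genomeT"), "gene rank"),
                 main = sub("__", " vs ", pair), ...)
  invisible(dt)
}

#' @export
plot.riparian_layout <- function(x, col = grDevices::adjustcolor("steelblue", 0.4),
                                 highlight_col = grDevices::adjustcolor("goldenrod", 0.7),
                                 ...) {
  seg <- x$segments
  graphics::plot(NA, xlim = c(0, 1), ylim = c(-0.2, max(seg$y) + 0.2),
                 xlab = "", ylab = "", axes = FALSE, ...)
  hlk <- paste(x$highlight$genome, x$highlight$chrom)
  for (i in seq_len(nrow(seg))) {
    graphics::rect(seg$x0[i], seg$y[i] - 0.05, seg$x1[i], seg$y[i] + 0.05,
                   col = if (paste(seg$genome[i], seg$chrom[i]) %in% hlk)
                     "goldenrod" else "grey40", border = NA)
  }
  gy <- unique(seg[, c("genome", "y")])
  graphics::text(-0.01, gy$y, gy$genome, adj = 1, xpd = NA, cex = 0.8)
  if (nrow(x$braids)) {
    for (i in seq_len(nrow(x$braids))) {
      b <- x$braids[i]
      hl <- paste(b$topGenome, b$chromTop) %in% hlk
      graphics::polygon(
        c(b$xTop0, b$xTop1, b$xBot1, b$xBot0),
        c(b$yTop - 0.05, b$yTop - 0.05, b$yBot + 0.05, b$yBot + 0.05),
        col = if (hl) highlight_col else col, border = NA)
    }
  }
  invisible(x)
}
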