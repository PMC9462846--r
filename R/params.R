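#' Tunable parameters for synteny and pan-genome construction
#'
#' Builds the single parameter object consumed by every stage of the pipeline.
#' All distances are in gene rank-order units (not bp): synteny inference runs
#' entirely in rank space so that gene density differences between genomes do
#' not distort block calling.
#'
#' @param blkSize minimum number of unique collinear hits required to call a
#'   syntenic block (also the minPts of the block-clustering DBSCAN).
#' @param nGaps maximum number of skipped rank positions between consecutive
#'   hits of a collinear chain, per axis.
#' @param synBuff radius (gene-rank units) around a syntenic anchor within
#'   which a hit is considered syntenic; also the tandem-array gap threshold
#'   and the region-clustering DBSCAN radius.
#' @param nHits1,nHits2 top-n score-rank cutoffs for query/target genes when
#'   flagging potential anchors. `"auto"` resolves nHits1 to the ploidy of the
#'   target genome and nHits2 to the ploidy of the query genome.
#' @param onlyOgAnchors must both genes of an anchor share an orthogroup?
#' @param nSecondaryHits number of paralogous (e.g. homeologous) copies to
#'   search for after masking primary syntenic regions; 0 disables the scan.
#' @param blkSizeSecond,nGapsSecond,synBuffSecond parameter set used by the
#'   secondary (paralog) scan; default to the primary values.
#' @param propAssignThresh minimum proportion of a syntenic orthogroup's
#'   positioned members that a positional cluster must hold to be retained as
#'   a pan-genome placement.
#' @param maxPlacementsPerRefChr maximum pan-genome placements of one syntenic
#'   orthogroup on one reference chromosome.
#' @param ploidy named integer vector, ploidy per genome; genomes not named
#'   default to 1.
#' @param outgroups character vector of genomes used only for orthogroup
#'   input and excluded from synteny and pan-genome stages.
#' @param orthofinderInBlk re-estimate orthogroups within syntenic regions and
#'   rerun synteny with the combined labels. `NA` (default) enables this
#'   exactly when any genome has ploidy > 1.
#' @param selfMaskRadius rank radius around the self-hit diagonal masked
#'   before scanning a polyploid genome against itself for homeologs.
#'
#' @return an object of class `synteny_params` (a validated named list).
#' @examples
#' p <- synteny_params(ploidy = c(maize = 2))
#' p$blkSize
#' @export
synteny_params <- function(blkSize = 5L,
                           nGaps = 5L,
                           synBuff = 100L,
                           nHits1 = "auto",
                           nHits2 = "auto",
                           onlyOgAnchors = TRUE,
                           nSecondaryHits = 0L,
                           blkSizeSecond = blkSize,
                           nGapsSecond = nGaps,
                           synBuffSecond = synBuff,
                           propAssignThresh = 0.5,
                           maxPlacementsPerRefChr = 2L,
                           ploidy = integer(),
                           outgroups = character(),
                           orthofinderInBlk = NA,
                           selfMaskRadius = 500L) {
  chk_int1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
      stop(nm, " must be a single integer >= 1", call. = FALSE)
    as.integer(x)
  }
  p <- list(
    blkSize = chk_int1(blkSize, "blkSize"),
    nGaps = chk_int1(nGaps, "nGaps"),
    synBuff = chk_int1(synBuff, "synBuff"),
    nHits1 = nHits1,
    nHits2 = nHits2,
    onlyOgAnchors = isTRUE(onlyOgAnchors),
    nSecondaryHits = as.integer(nSecondaryHits),
    blkSizeSecond = chk_int1(blkSizeSecond, "blkSizeSecond"),
    nGapsSecond = chk_int1(nGapsSecond, "nGapsSecond"),
    synBuffSecond = chk_int1(synBuffSecond, "synBuffSecond"),
    propAssignThresh = propAssignThresh,
    maxPlacementsPerRefChr = chk_int1(maxPlacementsPerRefChr,
                                      "maxPlacementsPerRefChr"),
    ploidy = ploidy,
    outgroups = as.character(outgroups),
    orthofinderInBlk = orthofinderInBlk,
    selfMaskRadius = chk_int1(selfMaskRadius, "selfMaskRadius")
  )
  if (p$nSecondaryHits < 0L)
    stop("nSecondaryHits must be >= 0", call. = FALSE)
  if (!is.numeric(p$propAssignThresh) || p$propAssignThresh <= 0 ||
      p$propAssignThresh > 1)
    stop("propAssignThresh must be in (0, 1]", call. = FALSE)
  for (nm in c("nHits1", "nHits2")) {
    v <- p[[nm]]
    if (!(identical(v, "auto") ||
          (is.numeric(v) && length(v) == 1L && v >= 1 && v == round(v))))
      stop(nm, " must be \"auto\" or an integer >= 1", call. = FALSE)
    if (is.numeric(v)) p[[nm]] <- as.integer(v)
  }
  if (length(p$ploidy)) {
    if (is.null(names(p$ploidy)) || any(names(p$ploidy) == ""))
      stop("ploidy must be a named vector (genome = ploidy)", call. = FALSE)
    if (any(p$ploidy < 1 | p$ploidy != round(p$ploidy)))
      stop("all ploidies must be integers >= 1", call. = FALSE)
    p$ploidy <- stats::setNames(as.integer(p$ploidy), names(p$ploidy))
  }
  structure(p, class = "synteny_params")
}

#' @export
print.synteny_params <- function(x, ...) {
  cat("Synteny parameters\n")
  cat(sprintf("  blkSize=%d nGaps=%d synBuff=%d\n",
              x$blkSize, x$nGaps, x$synBuff))
  cat(sprintf("  nHits1=%s nHits2=%s onlyOgAnchors=%s\n",
              as.character(x$nHits1), as.character(x$nHits2),
              x$onlyOgAnchors))
  cat(sprintf("  nSecondaryHits=%d (second: blkSize=%d nGaps=%d synBuff=%d)\n",
              x$nSecondaryHits, x$blkSizeSecond, x$nGapsSecond,
              x$synBuffSecond))
  cat(sprintf("  pangenome: propAssignThresh=%.2f maxPlacementsPerRefChr=%d\n",
              x$propAssignThresh, x$maxPlacementsPerRefChr))
  if (length(x$ploidy))
    cat("  ploidy:", paste0(names(x$ploidy), "=", x$ploidy, collapse = " "),
        "\n")
  if (length(x$outgroups))
    cat("  outgroups:", paste(x$outgroups, collapse = ", "), "\n")
  invisible(x)
}

ploidy_of <- function(params, genome) {
  if (genome %in% names(params$ploidy)) params$ploidy[[genome]] else 1L
}

resolve_nhits <- function(params, genomeQ, genomeT) {
  n1 <- if (identical(params$nHits1, "auto")) ploidy_of(params, genomeT)
        else params$nHits1
  n2 <- if (identical(params$nHits2, "auto")) ploidy_of(params, genomeQ)
        else params$nHits2
  c(nHits1 = as.integer(n1), nHits2 = as.integer(n2))
}
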