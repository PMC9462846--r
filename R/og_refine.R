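#' Re-estimate orthogroups within syntenic regions
#'
#' Within every syntenic region of every genome pair, genes are re-clustered
#' into in-block orthogroups (`inBlkOG`) as the connected components of the
#' reciprocal-best-hit graph restricted to in-buffer hits: a hit is an RBH
#' edge when its bitscore is maximal among the query gene's in-region hits
#' and maximal among the target gene's in-region hits (ties kept). This
#' rescues homeolog resolution inside syntenic context where a global
#' orthogroup lumps whole-genome-duplication paralog columns together. It is
#' a behavioral substitute for rerunning a full orthogrouping tool per
#' region, not a clone of one.
#'
#' @param pair_results list of per-pair `list(hits, blocks)` results.
#' @return named character vector gene_id -> inBlkOG label (only genes that
#'   participate in at least one in-buffer RBH edge are named).
#' @export
in_block_orthogroups <- function(pair_results) {
  edges_q <- character(0); edges_t <- character(0)
  for (pr in pair_results) {
    h <- pr$hits
    hb <- h[h$inBuffer & !is.na(h$reg_id)]
    if (!nrow(hb)) next
    for (rg in unique(hb$reg_id)) {
      hr <- hb[hb$reg_id == rg]
      bestQ <- stats::ave(hr$bitscore, hr$query, FUN = max)
      bestT <- stats::ave(hr$bitscore, hr$target, FUN = max)
      rbh <- hr$bitscore >= bestQ & hr$bitscore >= bestT
      edges_q <- c(edges_q, hr$query[rbh])
      edges_t <- c(edges_t, hr$target[rbh])
    }
  }
  if (!length(edges_q)) return(stats::setNames(character(0), character(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_q, to = edges_t), directed = FALSE)
  comp <- igraph::components(g)$membership
  # stable labels: number components by their lexicographically first gene
  first_gene <- tapply(names(comp), comp, min)
  relab <- stats::setNames(sprintf("iOG%06d", rank(first_gene)),
                           names(first_gene))
  stats::setNames(unname(relab[as.character(comp)]), names(comp))
}

#' Aggregate pairwise syntenic orthologs into syntenic orthogroups
#'
#' Builds a graph over all genes with one edge per syntenic hit (in-buffer
#' and sharing an orthogroup) across every genome pair; connected components
#' become syntenic orthogroups. Tandem-array members inherit their
#' representative's component; genes with no syntenic edge form singleton
#' groups so that the components partition the whole gene universe.
#'
#' @param scan a `synteny_scan` object ([run_synteny()]).
#' @return `data.table` with columns gene_id, genome, sog_id, provenance
#'   (`"in_block"` where the combined in-block labels connected the pair,
#'   otherwise `"global"`).
#' @export
syntenic_orthogroups <- function(scan) {
  genes <- scan$genes
  edges_q <- character(0); edges_t <- character(0)
  for (pr in scan$pairs) {
    h <- pr$hits
    syn <- h$inBuffer & h$isOg
    edges_q <- c(edges_q, h$query[syn])
    edges_t <- c(edges_t, h$target[syn])
  }
  universe <- genes$gene_id
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_q, to = edges_t), directed = FALSE,
    vertices = data.frame(name = universe))
  comp <- igraph::components(g)$membership[universe]
  # tandem members join their representative's component
  arr <- genes[!is.na(genes$array_id)]
  if (nrow(arr)) {
    rep_of <- arr[arr$is_array_rep]
    rep_comp <- comp[match(rep_of$gene_id, universe)]
    names(rep_comp) <- rep_of$array_id
    mem_idx <- which(!is.na(genes$array_id) & !genes$is_array_rep)
    comp[mem_idx] <- rep_comp[genes$array_id[mem_idx]]
  }
  first_gene <- tapply(universe, comp, min)
  relab <- stats::setNames(sprintf("sog%06d", rank(first_gene)),
                           names(first_gene))
  prov <- if (isTRUE(scan$used_in_block_og)) "in_block" else "global"
  data.table::data.table(
    gene_id = universe,
    genome = genes$genome,
    sog_id = unname(relab[as.character(comp)]),
    provenance = prov)
}
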