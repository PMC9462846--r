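#' Chain collinear hits in rank space
#'
#' Extracts maximal-scoring collinear chains from a set of hits placed at
#' condensed rank positions (x on the query axis, y on the target axis).
#' A chain is a sequence of hits strictly increasing in x with y strictly
#' monotone (increasing = "+" chain, decreasing = "-" chain), where
#' consecutive hits skip at most `nGaps` rank positions on each axis:
#' `(x[i+1] - x[i] - 1) <= nGaps` and `(|y[i+1] - y[i]| - 1) <= nGaps`.
#' Chains are scored by hit count and extracted greedily: the best chain
#' (ties: smaller minimum x, then smaller minimum y, then "+" before "-")
#' is removed and the search repeats until no chain of at least `blkSize`
#' hits remains. Every retained hit belongs to exactly one chain.
#'
#' This is the package's replacement for external collinearity callers: the
#' `-s`/`-m` semantics (minimum block size / maximum gaps) are kept, with a
#' fully deterministic extraction order.
#'
#' @param x,y integer condensed rank positions, one hit per element; no
#'   duplicated (x, y) pair.
#' @param blkSize minimum chain size retained.
#' @param nGaps per-axis gap cap between consecutive chain members.
#' @return list of chains; each chain is `list(idx, orientation)` where
#'   `idx` indexes into the input vectors and `orientation` is "+" or "-".
#' @export
chain_collinear <- function(x, y, blkSize, nGaps) {
  stopifnot(length(x) == length(y))
  if (anyDuplicated(cbind(x, y)))
    stop("duplicated (x, y) hit positions are not allowed")
  alive <- seq_along(x)
  chains <- list()
  while (length(alive) >= blkSize) {
    cp <- best_chain_dp(x[alive], y[alive], nGaps, orientation = "+")
    cm <- best_chain_dp(x[alive], y[alive], nGaps, orientation = "-")
    pick <- pick_chain(cp, cm, x[alive], y[alive])
    if (is.null(pick) || length(pick$idx) < blkSize) break
    chains[[length(chains) + 1L]] <-
      list(idx = alive[pick$idx], orientation = pick$orientation)
    alive <- alive[-pick$idx]
  }
  chains
}

# Single best chain for one orientation by O(n^2) dynamic programming.
# Returns list(idx (in input order along the chain), orientation) or NULL.
best_chain_dp <- function(x, y, nGaps, orientation) {
  n <- length(x)
  if (!n) return(NULL)
  sgn <- if (orientation == "+") 1L else -1L
  o <- order(x, sgn * y)
  xs <- x[o]; ys <- sgn * y[o]
  dp <- rep(1L, n)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1L]) {
    j <- seq_len(i - 1L)
    dx <- xs[i] - xs[j]
    dy <- ys[i] - ys[j]
    ok <- dx >= 1L & dy >= 1L & (dx - 1L) <= nGaps & (dy - 1L) <= nGaps
    if (any(ok)) {
      cand <- j[ok]
      m <- max(dp[cand])
      dp[i] <- m + 1L
      # predecessor tie-break: earliest in (x, y) sort order
      pred[i] <- cand[dp[cand] == m][1L]
    }
  }
  s <- max(dp)
  end <- which(dp == s)[1L]
  idx <- integer(s)
  k <- s; cur <- end
  while (!is.na(cur)) {
    idx[k] <- cur
    k <- k - 1L
    cur <- pred[cur]
  }
  list(idx = o[idx], orientation = orientation, score = s)
}

# Chooses between the best "+" and "-" chains: higher score, then smaller
# min-x, then smaller min-y, then "+".
pick_chain <- function(cp, cm, x, y) {
  if (is.null(cp)) return(cm)
  if (is.null(cm)) return(cp)
  if (cp$score != cm$score) return(if (cp$score > cm$score) cp else cm)
  kp <- c(min(x[cp$idx]), min(y[cp$idx]))
  km <- c(min(x[cm$idx]), min(y[cm$idx]))
  if (kp[1L] != km[1L]) return(if (kp[1L] < km[1L]) cp else cm)
  if (kp[2L] != km[2L]) return(if (kp[2L] < km[2L]) cp else cm)
  cp
}
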