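# Deterministic DBSCAN in rank space.
#
# Classic DBSCAN with Euclidean distance, specialised for the small 2-D
# point sets (anchor hits on one chromosome pair) this package clusters.
# Determinism contract: points are processed in sorted (x, y) order and
# border points join the first core cluster that reaches them, so identical
# input always yields identical labels regardless of input row order.
#
# Returns an integer vector of cluster labels aligned with the input;
# 0 marks noise. Self counts as a neighbor, so a lone point is core iff
# minPts <= 1.
dbscan_xy <- function(x, y, eps, minPts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  o <- order(x, y)
  xs <- x[o]; ys <- y[o]
  eps2 <- eps * eps
  nbr <- vector("list", n)
  cnt <- integer(n)
  # points are x-sorted: only a window with |dx| <= eps can be a neighbor
  j0 <- 1L
  for (i in seq_len(n)) {
    while (xs[i] - xs[j0] > eps) j0 <- j0 + 1L
    j <- i
    hi <- i
    while (hi < n && xs[hi + 1L] - xs[i] <= eps) hi <- hi + 1L
    idx <- j0:hi
    d2 <- (xs[idx] - xs[i])^2 + (ys[idx] - ys[i])^2
    nb <- idx[d2 <= eps2]
    nbr[[i]] <- nb
    cnt[i] <- length(nb)
  }
  core <- cnt >= minPts
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- nbr[[i]]
    while (length(queue)) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      if (lab[q] == 0L) {
        lab[q] <- cl
        if (core[q]) queue <- c(queue, nbr[[q]][lab[nbr[[q]]] == 0L])
      }
    }
  }
  out <- integer(n)
  out[o] <- lab
  out
}
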