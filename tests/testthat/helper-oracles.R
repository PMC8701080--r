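# Independent oracles and small fixture builders, used across test files.

# nested-path clone matrix: K clones on a linear chain, cellsPerClone cells
# each, clone k mutated at sites 1..(k*sitesPerStep)
makePathCloneMatrix <- function(K = 4, cellsPerClone = 5, sitesPerStep = 5) {
  m <- (K - 1) * sitesPerStep
  clones <- t(vapply(seq_len(K) - 1L, function(k)
    as.integer(seq_len(m) <= k * sitesPerStep), integer(m)))
  labels <- rep(seq_len(K) - 1L, each = cellsPerClone)
  list(calls = clones[labels + 1L, , drop = FALSE], labels = labels,
       clones = clones)
}

# decode a Pruefer sequence into the edge matrix of its labeled tree
pruferToEdges <- function(pr, K) {
  degree <- rep(1L, K)
  for (p in pr) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, K - 1L, 2L)
  e <- 1L
  for (p in pr) {
    leaf <- which(degree == 1L)[1L]
    edges[e, ] <- c(leaf, p); e <- e + 1L
    degree[leaf] <- 0L
    degree[p] <- degree[p] - 1L
  }
  edges[e, ] <- which(degree == 1L)
  edges
}

# minimum spanning-tree weight by exhaustive Cayley enumeration (K^(K-2)
# labeled trees); tractable for K <= 6
bruteForceMSTWeight <- function(D) {
  K <- nrow(D)
  if (K == 1L) return(0)
  if (K == 2L) return(D[1L, 2L])
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), K - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- pruferToEdges(as.integer(seqs[r, ]), K)
    best <- min(best, sum(D[ed]))
  }
  best
}

# ARI by direct pair counting over all item pairs -- no contingency table,
# independent of the implementation's route
ariPairCounts <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# quiet pipeline helpers (the iteration cap warning is expected at desk scale)
quietDecompose <- function(...) suppressWarnings(rdaDecompose(...))
quietPipeline <- function(...) suppressWarnings(runPipeline(...))
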