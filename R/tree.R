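#' Consensus genotype of each subclone
#'
#' Per subclone and per site, the majority call among member cells; exact
#' ties resolve to 0, biasing toward the unmutated ancestral state.
#'
#' @param calls n x m matrix of genotype calls in \{0,1\}.
#' @param assignment a [SubcloneAssignment-class] (or integer vector of
#'   0-based labels).
#' @return K x m integer matrix; row k is the consensus of subclone k-1.
#' @export
consensusGenotypes <- function(calls, assignment) {
  labels <- if (is(assignment, "SubcloneAssignment"))
    assignment@labels else as.integer(assignment)
  if (length(labels) != nrow(calls))
    stop("one label per cell required")
  K <- max(labels) + 1L
  cons <- matrix(0L, K, ncol(calls))
  for (k in seq_len(K) - 1L) {
    members <- calls[labels == k, , drop = FALSE]
    if (nrow(members) == 0L) stop("empty subclone ", k, " in the partition")
    cons[k + 1L, ] <- as.integer(colMeans(members) > 0.5)  # tie (0.5) -> 0
  }
  cons
}

#' Pairwise Euclidean distances between subclone genotypes
#'
#' @param consensus K x m matrix of consensus genotypes.
#' @return K x K symmetric numeric matrix with zero diagonal.
#' @export
subcloneDistances <- function(consensus) {
  as.matrix(stats::dist(consensus))
}

#' Minimum spanning tree of a distance matrix
#'
#' Deterministic Kruskal: edges are processed in increasing weight, with
#' equal-weight ties broken by lexicographically smallest (a, b) pair — ties
#' are common on binary genotypes, so the order is pinned down explicitly.
#'
#' @param D K x K symmetric non-negative distance matrix with zero diagonal.
#' @return data.frame with columns \code{from}, \code{to} (0-based subclone
#'   labels, from < to) and \code{weight}; K-1 rows (empty for K = 1).
#' @export
minimumSpanningTree <- function(D) {
  D <- as.matrix(D)
  K <- nrow(D)
  if (K == 0L) stop("empty distance matrix")
  if (!isTRUE(all.equal(D, t(D))) || any(D < 0) || any(diag(D) != 0))
    stop("'D' must be symmetric and non-negative with a zero diagonal")
  empty <- data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  if (K == 1L) return(empty)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  cand <- data.frame(from = idx[, 1L], to = idx[, 2L], weight = D[idx])
  cand <- cand[order(cand$weight, cand$from, cand$to), , drop = FALSE]
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- empty
  for (r in seq_len(nrow(cand))) {
    a <- find(cand$from[r]); b <- find(cand$to[r])
    if (a != b) {
      parent[a] <- b
      picked <- rbind(picked, cand[r, ])
      if (nrow(picked) == K - 1L) break
    }
  }
  picked$from <- picked$from - 1L
  picked$to <- picked$to - 1L
  rownames(picked) <- NULL
  picked
}

# recursive Newick serialization; nodes carry subclone labels, branch lengths
# are the MST edge weights
.newickString <- function(children, weights, node, root) {
  kids <- children[[node + 1L]]
  lab <- sprintf("subclone_%d", node)
  inner <- if (length(kids) == 0L) lab else {
    sub <- vapply(kids, function(k)
      paste0(.newickString(children, weights, k, root), ":",
             format(weights[[paste(node, k)]], digits = 15)), "")
    paste0("(", paste(sub, collapse = ","), ")", lab)
  }
  inner
}

#' Root a spanning tree at the most-normal subclone
#'
#' The root is the subclone with the fewest mutations in its consensus
#' genotype (the most-normal genotype; ties go to the lowest label). Edges
#' are oriented away from the root and the tree is serialized to Newick with
#' the Euclidean edge weights as branch lengths.
#'
#' @param edges undirected spanning-tree edge list from
#'   [minimumSpanningTree()].
#' @param consensus K x m consensus genotype matrix.
#' @return a [SubcloneTree-class].
#' @export
rootTree <- function(edges, consensus) {
  K <- nrow(consensus)
  burden <- rowSums(consensus)
  root <- which.min(burden) - 1L   # ties -> lowest label (which.min convention)
  if (K == 1L) {
    return(new("SubcloneTree", consensus = consensus,
               edges = data.frame(parent = integer(0), child = integer(0),
                                  weight = numeric(0)),
               root = 0L, newick = "subclone_0;"))
  }
  if (nrow(edges) != K - 1L) stop("'edges' must be a spanning tree (K-1 edges)")
  adj <- vector("list", K)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]
    adj[[a + 1L]] <- rbind(adj[[a + 1L]], c(b, edges$weight[r]))
    adj[[b + 1L]] <- rbind(adj[[b + 1L]], c(a, edges$weight[r]))
  }
  children <- vector("list", K)
  weights <- list()
  visited <- rep(FALSE, K)
  queue <- root; visited[root + 1L] <- TRUE
  oriented <- data.frame(parent = integer(0), child = integer(0), weight = numeric(0))
  while (length(queue) > 0L) {
    node <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[node + 1L]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      ch <- as.integer(nb[r, 1L])
      if (!visited[ch + 1L]) {
        visited[ch + 1L] <- TRUE
        children[[node + 1L]] <- c(children[[node + 1L]], ch)
        weights[[paste(node, ch)]] <- nb[r, 2L]
        oriented <- rbind(oriented,
                          data.frame(parent = node, child = ch, weight = nb[r, 2L]))
        queue <- c(queue, ch)
      }
    }
  }
  if (!all(visited)) stop("'edges' do not connect all subclones")
  newick <- paste0(.newickString(children, weights, root, root), ";")
  new("SubcloneTree", consensus = consensus, edges = oriented,
      root = root, newick = newick)
}

#' Build the rooted subclone evolutionary tree from genotype calls
#'
#' Chains [consensusGenotypes()], [subcloneDistances()],
#' [minimumSpanningTree()] and [rootTree()].
#'
#' @param calls n x m matrix of genotype calls.
#' @param assignment a [SubcloneAssignment-class].
#' @return a [SubcloneTree-class].
#' @export
buildSubcloneTree <- function(calls, assignment) {
  cons <- consensusGenotypes(calls, assignment)
  rootTree(minimumSpanningTree(subcloneDistances(cons)), cons)
}
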