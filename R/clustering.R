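#' Configuration of Louvain-Jaccard subclone clustering
#'
#' @param kNeighbors neighbors per cell in the kNN graph (clamped to n-1 at
#'   run time, with a warning).
#' @param resolution modularity resolution of Louvain; 1 is the classic
#'   modularity. Clustering accuracy on clone-structured genotype data is
#'   robust to this choice, which is asserted by test rather than assumed.
#' @param seed integer seed controlling Louvain tie-breaking.
#' @param minClusterSize clusters smaller than this are merged into the
#'   nearest cluster by consensus-genotype Euclidean distance; the default 1
#'   disables merging.
#' @return a list of class \code{clusterConfig}.
#' @export
clusterConfig <- function(kNeighbors = 20L, resolution = 1, seed = 1L,
                          minClusterSize = 1L) {
  if (kNeighbors < 1L) stop("'kNeighbors' must be >= 1")
  if (resolution <= 0) stop("'resolution' must be positive")
  if (minClusterSize < 0L) stop("'minClusterSize' must be >= 0")
  structure(list(kNeighbors = as.integer(kNeighbors), resolution = resolution,
                 seed = as.integer(seed), minClusterSize = as.integer(minClusterSize)),
            class = "clusterConfig")
}

#' k-nearest neighbors of each cell under Euclidean genotype distance
#'
#' Distance ties are broken by lower cell index, making the neighbor sets
#' deterministic.
#'
#' @param G n x m matrix of genotype calls (rows are cells).
#' @param k number of neighbors; clamped to n-1 with a warning when too large.
#' @return list of n integer vectors of neighbor indices.
#' @export
knnNeighbors <- function(G, k) {
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 cells")
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; clamped to %d", k, n, n - 1L))
    k <- n - 1L
  }
  D <- as.matrix(stats::dist(G))
  lapply(seq_len(n), function(i) {
    o <- order(D[i, ], seq_len(n))   # ties -> lower index first
    o <- o[o != i]
    o[seq_len(k)]
  })
}

#' Shared-nearest-neighbor Jaccard edge weights
#'
#' For every pair (i, j) with j in N(i) or i in N(j), the edge weight is the
#' Jaccard similarity of the two neighbor sets,
#' |N(i) n N(j)| / |N(i) u N(j)|; zero-weight edges are dropped.
#'
#' @param neighbors list of integer neighbor vectors from [knnNeighbors()].
#' @return data.frame with columns \code{from}, \code{to} (1-based cell
#'   indices, from < to) and \code{weight}.
#' @export
jaccardEdges <- function(neighbors) {
  n <- length(neighbors)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) A[i, neighbors[[i]]] <- 1L
  cand <- which((A == 1L | t(A) == 1L) & upper.tri(A), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(from = integer(0), to = integer(0), weight = numeric(0)))
  inter <- tcrossprod(A)  # |N(i) n N(j)|
  ki <- rowSums(A)
  i <- cand[, 1L]; j <- cand[, 2L]
  w <- inter[cand] / (ki[i] + ki[j] - inter[cand])
  keep <- w > 0
  out <- data.frame(from = i[keep], to = j[keep], weight = w[keep])
  out[order(out$from, out$to), , drop = FALSE]
}

# renumber integer cluster ids so the largest cluster gets 0-based label 0;
# size ties broken by first occurrence
.renumberBySize <- function(member) {
  sz <- table(member)
  first <- vapply(names(sz), function(g) which(member == g)[1L], 1L)
  ord <- names(sz)[order(-as.integer(sz), first)]
  newLab <- stats::setNames(seq_along(ord) - 1L, ord)
  as.integer(newLab[as.character(member)])
}

#' Louvain community detection on a weighted cell graph
#'
#' Runs modularity-maximizing Louvain clustering at the given resolution on
#' the Jaccard-weighted graph. Labels are renumbered by decreasing cluster
#' size (largest = 0). Clusters smaller than \code{minClusterSize} are merged
#' into the nearest cluster by consensus-genotype Euclidean distance, which
#' requires \code{genotypes}.
#'
#' @param edges data.frame from [jaccardEdges()].
#' @param nCells total number of cells (isolated cells are allowed and become
#'   their own community).
#' @param config a [clusterConfig()].
#' @param genotypes optional n x m call matrix, needed only when
#'   \code{minClusterSize > 1}.
#' @return a [SubcloneAssignment-class].
#' @export
louvainCluster <- function(edges, nCells, config = clusterConfig(),
                           genotypes = NULL) {
  if (nrow(edges) == 0L) {
    warning("empty edge list: every cell becomes its own cluster")
    return(new("SubcloneAssignment",
               labels = seq_len(nCells) - 1L, nSubclones = as.integer(nCells)))
  }
  g <- igraph::make_empty_graph(nCells, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  set.seed(config$seed %% .Machine$integer.max)
  comm <- igraph::cluster_louvain(g, weights = edges$weight,
                                  resolution = config$resolution)
  member <- as.integer(igraph::membership(comm))
  if (config$minClusterSize > 1L && !is.null(genotypes)) {
    repeat {
      sz <- table(member)
      small <- names(sz)[as.integer(sz) < config$minClusterSize]
      if (length(small) == 0L || length(sz) == 1L) break
      cons <- do.call(rbind, lapply(names(sz), function(gid)
        colMeans(genotypes[member == as.integer(gid), , drop = FALSE])))
      rownames(cons) <- names(sz)
      s <- small[1L]
      d <- sqrt(rowSums(sweep(cons, 2L, cons[s, ], "-")^2))
      d[s] <- Inf
      member[member == as.integer(s)] <- as.integer(names(which.min(d)))
    }
  }
  labels <- .renumberBySize(member)
  new("SubcloneAssignment", labels = labels,
      nSubclones = as.integer(max(labels) + 1L))
}

#' Cluster cells into subclones from genotype calls
#'
#' Convenience wrapper chaining [knnNeighbors()], [jaccardEdges()] and
#' [louvainCluster()]. Distances are computed on binarized genotype calls,
#' not on the continuous recovered matrix, so the clustering is invariant to
#' its scale.
#'
#' @param calls n x m matrix of genotype calls.
#' @param config a [clusterConfig()].
#' @return a [SubcloneAssignment-class].
#' @examples
#' G <- rbind(matrix(0, 10, 6), matrix(1, 10, 6))
#' table(subcloneLabels(clusterSubclones(G, clusterConfig(kNeighbors = 5))))
#' @export
clusterSubclones <- function(calls, config = clusterConfig()) {
  nb <- knnNeighbors(calls, config$kNeighbors)
  ed <- jaccardEdges(nb)
  louvainCluster(ed, nrow(calls), config, genotypes = calls)
}
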