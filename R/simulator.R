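#' Configuration of the clone-structured SCGS simulator
#'
#' Defaults other than the required sizes follow the fixed operating point of
#' the factorial simulation design this generator emulates: FPR = 0.15,
#' FNR = 0.15, MR = 0.3.
#'
#' @param nCells number of cells (rows).
#' @param nSites number of genotype sites (columns).
#' @param nSubclones number of subclones including the unmutated root clone.
#' @param fpr false-positive rate in [0,1): probability a true 0 is observed
#'   as 1 (amplification artifact).
#' @param fnr false-negative rate in [0,1): probability a true 1 is observed
#'   as 0 (allelic dropout).
#' @param mr missing rate in [0,1]: probability an entry has no call;
#'   missingness is applied after the flips, masking them.
#' @param seed integer seed.
#' @param minCellsPerClone guaranteed cells per clone (default 3, so
#'   consensus genotypes are majority-defined).
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nCells, nSites, nSubclones, fpr = 0.15,
                             fnr = 0.15, mr = 0.3, seed = 1L,
                             minCellsPerClone = 3L) {
  nCells <- as.integer(nCells); nSites <- as.integer(nSites)
  nSubclones <- as.integer(nSubclones)
  minCellsPerClone <- as.integer(minCellsPerClone)
  if (nCells < 2L || nSites < 1L || nSubclones < 1L || minCellsPerClone < 1L)
    stop("sizes must be positive (and nCells >= 2)")
  if (fpr < 0 || fpr >= 1 || fnr < 0 || fnr >= 1 || mr < 0 || mr > 1)
    stop("rates must satisfy fpr, fnr in [0,1) and mr in [0,1]")
  if (nSubclones > nCells %/% minCellsPerClone)
    stop("infeasible: nSubclones > nCells / minCellsPerClone")
  if (nSubclones > nSites + 1L)
    stop("infeasible: each non-root clone needs >= 1 private site (nSubclones > nSites + 1)")
  structure(list(nCells = nCells, nSites = nSites, nSubclones = nSubclones,
                 fpr = fpr, fnr = fnr, mr = mr, seed = as.integer(seed),
                 minCellsPerClone = minCellsPerClone),
            class = "simulationConfig")
}

#' Simulate a random clonal tree and clone genotypes
#'
#' A uniform-attachment random recursive tree: subclone 0 is the unmutated
#' root and each later subclone attaches to a uniformly drawn earlier one.
#' Every site is assigned to exactly one tree edge uniformly at random,
#' subject to each non-root clone receiving at least one private site
#' (infinite-sites placement, no back-mutation), and a clone's genotype is
#' the union of the mutations on its root path -- so child genotypes always
#' contain their parent's.
#'
#' @param nSubclones number of subclones (>= 1).
#' @param nSites number of genotype sites; must be >= nSubclones - 1.
#' @param seed integer seed.
#' @return list with \code{parent} (integer vector, \code{parent[k+1]} is the
#'   0-based parent of subclone k, NA for the root) and \code{cloneGenotypes}
#'   (K x m integer matrix).
#' @export
simulateCloneTree <- function(nSubclones, nSites, seed = 1L) {
  K <- as.integer(nSubclones); m <- as.integer(nSites)
  if (K < 1L) stop("need at least one subclone")
  if (K > m + 1L) stop("nSubclones > nSites + 1: not enough sites for private mutations")
  set.seed(seed %% .Machine$integer.max)
  parent <- rep(NA_integer_, K)
  if (K > 1L)
    parent[2:K] <- vapply(2:K, function(i) sample.int(i - 1L, 1L), 1L) - 1L
  geno <- matrix(0L, K, m)
  if (K > 1L) {
    # edge e ends at subclone e (1-based row e+1); each edge gets one site
    # first, the remainder is uniform
    edgeOfSite <- integer(m)
    edgeOfSite[seq_len(K - 1L)] <- seq_len(K - 1L)
    if (m > K - 1L)
      edgeOfSite[K:m] <- sample.int(K - 1L, m - K + 1L, replace = TRUE)
    edgeOfSite <- edgeOfSite[sample.int(m)]
    for (k in seq_len(K - 1L)) {         # 0-based subclone id k
      path <- k
      p <- parent[k + 1L]
      while (!is.na(p) && p != 0L) { path <- c(path, p); p <- parent[p + 1L] }
      geno[k + 1L, edgeOfSite %in% path] <- 1L
    }
  }
  list(parent = parent, cloneGenotypes = geno)
}

#' Assign cells to subclones
#'
#' Every clone receives \code{minCellsPerClone} cells; the remainder is
#' multinomial with uniform clone probabilities. The labels are then
#' shuffled across cells.
#'
#' @param nCells number of cells.
#' @param nSubclones number of subclones.
#' @param minCellsPerClone guaranteed cells per clone.
#' @param seed integer seed.
#' @return integer vector of 0-based clone labels, one per cell.
#' @export
assignCells <- function(nCells, nSubclones, minCellsPerClone = 3L, seed = 1L) {
  n <- as.integer(nCells); K <- as.integer(nSubclones)
  if (K * minCellsPerClone > n)
    stop("infeasible: nSubclones * minCellsPerClone > nCells")
  set.seed(seed %% .Machine$integer.max)
  counts <- rep(as.integer(minCellsPerClone), K)
  extra <- n - sum(counts)
  if (extra > 0L)
    counts <- counts + as.integer(stats::rmultinom(1L, extra, rep(1 / K, K)))
  labels <- rep(seq_len(K) - 1L, counts)
  labels[sample.int(n)]
}

#' Corrupt a clean genotype matrix with sequencing noise
#'
#' Independently per entry: a true 0 flips to 1 with probability \code{fpr},
#' a true 1 flips to 0 with probability \code{fnr}; each entry is then set
#' missing with probability \code{mr}. Missingness is applied after the
#' flips (masking them), so the realized missing rate is independent of the
#' flip rates.
#'
#' @param truth n x m binary matrix.
#' @param fpr,fnr,mr noise rates, see [simulationConfig()].
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class] with NA at missing entries.
#' @export
applyNoise <- function(truth, fpr, fnr, mr, seed = 1L) {
  stopifnot(all(truth %in% c(0L, 1L)))
  n <- nrow(truth); m <- ncol(truth)
  set.seed(seed %% .Machine$integer.max)
  u <- matrix(stats::runif(n * m), n, m)
  obs <- truth
  obs[truth == 0 & u < fpr] <- 1L
  obs[truth == 1 & u < fnr] <- 0L
  obs <- obs * 1.0
  miss <- matrix(stats::runif(n * m) < mr, n, m)
  obs[miss] <- NA_real_
  genotypeMatrix(obs, cellIds = rownames(truth), siteIds = colnames(truth))
}

#' Increase the missing rate of an observed matrix
#'
#' Uniformly samples currently observed entries and marks them missing until
#' the overall missing fraction reaches \code{targetMr} (rounded to the
#' nearest entry count), recording which entries were newly masked -- the
#' set needed to score imputation accuracy on real data.
#'
#' @param g a [GenotypeMatrix-class].
#' @param targetMr target overall missing fraction; must be at least the
#'   current one.
#' @param seed integer seed.
#' @return list with \code{genotypes} (the degraded [GenotypeMatrix-class])
#'   and \code{newlyMasked} (2-column matrix of row/col indices).
#' @export
degradeMissing <- function(g, targetMr, seed = 1L) {
  stopifnot(is(g, "GenotypeMatrix"))
  v <- g@values
  total <- length(v)
  current <- sum(is.na(v))
  target <- round(targetMr * total)
  if (target < current)
    stop(sprintf("targetMr %.3f is below the current missing fraction %.3f",
                 targetMr, current / total))
  extra <- target - current
  observedIdx <- which(!is.na(v))
  set.seed(seed %% .Machine$integer.max)
  newIdx <- if (extra > 0L) sample(observedIdx, extra) else integer(0)
  v[newIdx] <- NA_real_
  list(genotypes = genotypeMatrix(v, cellIds = g@cellIds, siteIds = g@siteIds),
       newlyMasked = arrayInd(newIdx, dim(v)))
}

#' Simulate a ground-truthed single-cell genotype dataset
#'
#' Composes [simulateCloneTree()], [assignCells()] and [applyNoise()]
#' (component seeds are \code{seed}, \code{seed + 1}, \code{seed + 2}) and
#' bundles the clean matrix, the observation, the true labels and the true
#' clone tree.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedGenotypes-class].
#' @examples
#' sim <- simulateDataset(simulationConfig(60, 40, 4, seed = 7))
#' sim
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  tree <- simulateCloneTree(config$nSubclones, config$nSites, seed = config$seed)
  labels <- assignCells(config$nCells, config$nSubclones,
                        config$minCellsPerClone, seed = config$seed + 1L)
  truth <- tree$cloneGenotypes[labels + 1L, , drop = FALSE]
  rownames(truth) <- sprintf("cell_%04d", seq_len(config$nCells))
  colnames(truth) <- sprintf("site_%04d", seq_len(config$nSites))
  observed <- applyNoise(truth, config$fpr, config$fnr, config$mr,
                         seed = config$seed + 2L)
  new("SimulatedGenotypes", truth = truth, observed = observed,
      trueLabels = labels, parent = tree$parent,
      cloneGenotypes = tree$cloneGenotypes, config = unclass(config))
}
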