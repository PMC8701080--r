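#' @import methods
NULL

MISSING_TOKENS_DEFAULT <- c("3", "NA", "-", "")

#' GenotypeMatrix: an observed single-cell SNV genotype matrix
#'
#' Cells are rows, genotype sites are columns. Entries are 0 (no mutation),
#' 1 (mutation) or \code{NA} (no call / missing base). The observed-index set
#' Omega is implicit: an entry is observed iff it is not \code{NA}.
#'
#' @slot values numeric matrix with entries in \{0, 1, NA\}; rows are cells.
#' @slot cellIds character vector of row labels.
#' @slot siteIds character vector of column labels.
#'
#' @seealso [genotypeMatrix()], [readGenotypeMatrix()], [encodeForRDA()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(values = "matrix", cellIds = "character", siteIds = "character"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L) return("need at least 2 cells (rows)")
  if (ncol(v) < 1L) return("need at least 1 genotype site (column)")
  ok <- is.na(v) | v == 0 | v == 1
  if (!all(ok)) return("entries must be 0, 1 or NA (missing)")
  if (length(object@cellIds) != nrow(v)) return("cellIds length != number of rows")
  if (length(object@siteIds) != ncol(v)) return("siteIds length != number of columns")
  if (anyDuplicated(object@cellIds)) return("duplicated cell ids")
  if (anyDuplicated(object@siteIds)) return("duplicated site ids")
  TRUE
})

#' RDADecomposition: result of the extended robust deep autoencoder
#'
#' Holds the low-rank recovered matrix LD, the sparse error matrix S, the
#' previous-iterate sum LS, the per-iteration convergence trace and the
#' binarized genotype calls.
#'
#' @slot LD numeric matrix, the recovered (low-rank) genotype matrix.
#' @slot S numeric matrix, the sparse error matrix; X = LD + S exactly on
#'   unobserved entries, and up to the shrinkage removal on observed ones.
#' @slot LS numeric matrix, LD + S from the last completed outer iteration.
#' @slot trace data.frame with columns \code{iteration}, \code{c1}, \code{c2},
#'   \code{nnz_S_observed}: the two Frobenius-ratio convergence checks and the
#'   number of surviving nonzero observed entries of S.
#' @slot genotypeCalls integer matrix in \{0,1\}: 1 where LD >= threshold.
#' @slot converged logical, whether c1 or c2 dropped below epsilon.
#' @slot iterationsRun integer number of outer iterations executed.
#' @slot lambda numeric, the sparsity weight actually used.
#' @slot threshold numeric, the binarization threshold used.
#'
#' @exportClass RDADecomposition
setClass("RDADecomposition",
  representation(LD = "matrix", S = "matrix", LS = "matrix",
                 trace = "data.frame", genotypeCalls = "matrix",
                 converged = "logical", iterationsRun = "integer",
                 lambda = "numeric", threshold = "numeric"))

setValidity("RDADecomposition", function(object) {
  d <- dim(object@LD)
  if (!identical(dim(object@S), d) || !identical(dim(object@LS), d) ||
      !identical(dim(object@genotypeCalls), d))
    return("LD, S, LS and genotypeCalls must share dimensions")
  if (!all(object@genotypeCalls %in% c(0L, 1L)))
    return("genotypeCalls must be binary")
  if (nrow(object@trace) != object@iterationsRun)
    return("trace must have one row per outer iteration")
  TRUE
})

#' SubcloneAssignment: per-cell subclone labels
#'
#' Labels are 0-based integers in \code{[0, K)}; label 0 is the largest
#' subclone (clusters are renumbered by decreasing size).
#'
#' @slot labels integer vector, one label per cell.
#' @slot nSubclones integer, the number K of subclones.
#'
#' @exportClass SubcloneAssignment
setClass("SubcloneAssignment",
  representation(labels = "integer", nSubclones = "integer"))

setValidity("SubcloneAssignment", function(object) {
  K <- object@nSubclones
  if (length(object@labels) < 1L) return("empty label vector")
  if (K < 1L) return("need at least one subclone")
  if (!all(object@labels %in% 0:(K - 1L))) return("labels must lie in [0, K)")
  if (!all(0:(K - 1L) %in% object@labels)) return("every label in [0, K) must occur")
  TRUE
})

#' SubcloneTree: consensus genotypes and the rooted minimum spanning tree
#'
#' @slot consensus K x m integer matrix in \{0,1\}, one consensus genotype row
#'   per subclone (row k is subclone k-1; labels are 0-based).
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{weight} (Euclidean distance); K-1 rows, oriented away from the root.
#' @slot root integer, 0-based label of the root (most-normal) subclone.
#' @slot newick character scalar, the rooted tree in Newick format with branch
#'   lengths equal to the MST edge weights.
#'
#' @exportClass SubcloneTree
setClass("SubcloneTree",
  representation(consensus = "matrix", edges = "data.frame",
                 root = "integer", newick = "character"))

setValidity("SubcloneTree", function(object) {
  K <- nrow(object@consensus)
  if (nrow(object@edges) != K - 1L) return("a spanning tree over K nodes has K-1 edges")
  if (K >= 1L && !(object@root %in% 0:(K - 1L))) return("root must be a subclone label")
  if (K > 1L) {
    # connectivity check: union-find over the edges
    parent <- seq_len(K)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(object@edges))) {
      a <- find(object@edges$parent[r] + 1L); b <- find(object@edges$child[r] + 1L)
      if (a == b) return("edges contain a cycle")
      parent[a] <- b
    }
  }
  TRUE
})

#' SimulatedGenotypes: a ground-truthed synthetic SCGS dataset
#'
#' @slot truth n x m integer matrix in \{0,1\}, the clean genotype matrix.
#' @slot observed [GenotypeMatrix-class], the noise-corrupted observation.
#' @slot trueLabels integer vector of 0-based subclone labels per cell.
#' @slot parent integer vector of length K: \code{parent[k+1]} is the 0-based
#'   parent of subclone k, \code{NA} for the root (subclone 0).
#' @slot cloneGenotypes K x m integer matrix of true clone genotypes.
#' @slot config list, the [simulationConfig()] used.
#'
#' @exportClass SimulatedGenotypes
setClass("SimulatedGenotypes",
  representation(truth = "matrix", observed = "GenotypeMatrix",
                 trueLabels = "integer", parent = "integer",
                 cloneGenotypes = "matrix", config = "list"))

setValidity("SimulatedGenotypes", function(object) {
  if (!identical(dim(object@truth), dim(object@observed@values)))
    return("truth and observed must share dimensions")
  if (length(object@trueLabels) != nrow(object@truth))
    return("one true label per cell required")
  K <- length(object@parent)
  if (sum(is.na(object@parent)) != 1L || !is.na(object@parent[1L]))
    return("exactly one root (subclone 0) allowed")
  if (K > 1L && !all(object@parent[-1L] >= 0 & object@parent[-1L] < seq_len(K - 1L)))
    return("parent of subclone k must be an earlier subclone (acyclic)")
  TRUE
})
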