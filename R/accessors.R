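#' Accessors for GenotypeMatrix and friends
#'
#' @param x a [GenotypeMatrix-class], [RDADecomposition-class],
#'   [SubcloneAssignment-class], [SubcloneTree-class] or
#'   [SimulatedGenotypes-class] object, as documented per generic.
#' @name accessors
NULL

#' @describeIn accessors numeric matrix of genotype values (NA = missing).
#' @export
setGeneric("genotypeValues", function(x) standardGeneric("genotypeValues"))

#' @describeIn accessors number of cells (rows).
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @describeIn accessors number of genotype sites (columns).
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn accessors cell identifiers.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @describeIn accessors site identifiers.
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @describeIn accessors fraction of entries that are missing.
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @describeIn accessors recovered low-rank matrix LD.
#' @export
setGeneric("recoveredMatrix", function(x) standardGeneric("recoveredMatrix"))

#' @describeIn accessors sparse error matrix S.
#' @export
setGeneric("sparseMatrixPart", function(x) standardGeneric("sparseMatrixPart"))

#' @describeIn accessors binarized genotype calls.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @describeIn accessors per-iteration convergence trace (c1, c2, nnz of S).
#' @export
setGeneric("convergenceTrace", function(x) standardGeneric("convergenceTrace"))

#' @describeIn accessors per-cell 0-based subclone labels.
#' @export
setGeneric("subcloneLabels", function(x) standardGeneric("subcloneLabels"))

#' @describeIn accessors number of subclones.
#' @export
setGeneric("nSubclones", function(x) standardGeneric("nSubclones"))

#' @describeIn accessors consensus genotype matrix (one row per subclone).
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @describeIn accessors oriented edge table of the subclone tree.
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @describeIn accessors 0-based label of the root subclone.
#' @export
setGeneric("treeRoot", function(x) standardGeneric("treeRoot"))

#' @describeIn accessors Newick serialization of the rooted subclone tree.
#' @export
setGeneric("treeNewick", function(x) standardGeneric("treeNewick"))

#' @describeIn accessors clean ground-truth matrix of a simulation.
#' @export
setGeneric("truthMatrix", function(x) standardGeneric("truthMatrix"))

#' @describeIn accessors observed (corrupted) GenotypeMatrix of a simulation.
#' @export
setGeneric("observedMatrix", function(x) standardGeneric("observedMatrix"))

#' @describeIn accessors true per-cell subclone labels of a simulation.
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @describeIn accessors true clone-tree parent array of a simulation.
#' @export
setGeneric("trueTreeParents", function(x) standardGeneric("trueTreeParents"))

setMethod("genotypeValues", "GenotypeMatrix", function(x) x@values)
setMethod("nCells", "GenotypeMatrix", function(x) nrow(x@values))
setMethod("nSites", "GenotypeMatrix", function(x) ncol(x@values))
setMethod("cellIds", "GenotypeMatrix", function(x) x@cellIds)
setMethod("siteIds", "GenotypeMatrix", function(x) x@siteIds)
setMethod("missingFraction", "GenotypeMatrix", function(x) mean(is.na(x@values)))
setMethod("dim", "GenotypeMatrix", function(x) dim(x@values))

setMethod("recoveredMatrix", "RDADecomposition", function(x) x@LD)
setMethod("sparseMatrixPart", "RDADecomposition", function(x) x@S)
setMethod("genotypeCalls", "RDADecomposition", function(x) x@genotypeCalls)
setMethod("convergenceTrace", "RDADecomposition", function(x) x@trace)

setMethod("subcloneLabels", "SubcloneAssignment", function(x) x@labels)
setMethod("nSubclones", "SubcloneAssignment", function(x) x@nSubclones)

setMethod("consensusMatrix", "SubcloneTree", function(x) x@consensus)
setMethod("treeEdges", "SubcloneTree", function(x) x@edges)
setMethod("treeRoot", "SubcloneTree", function(x) x@root)
setMethod("treeNewick", "SubcloneTree", function(x) x@newick)
setMethod("nSubclones", "SubcloneTree", function(x) nrow(x@consensus))

setMethod("truthMatrix", "SimulatedGenotypes", function(x) x@truth)
setMethod("observedMatrix", "SimulatedGenotypes", function(x) x@observed)
setMethod("trueLabels", "SimulatedGenotypes", function(x) x@trueLabels)
setMethod("trueTreeParents", "SimulatedGenotypes", function(x) x@parent)
setMethod("subcloneLabels", "SimulatedGenotypes", function(x) x@trueLabels)
setMethod("nSubclones", "SimulatedGenotypes", function(x) length(x@parent))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d cells x %d sites, %.1f%% missing\n",
              nrow(object@values), ncol(object@values),
              100 * mean(is.na(object@values))))
})

setMethod("show", "RDADecomposition", function(object) {
  n <- nrow(object@trace)
  cat(sprintf("RDADecomposition: %d x %d, %d outer iteration(s), %s\n",
              nrow(object@LD), ncol(object@LD), object@iterationsRun,
              if (object@converged) "converged" else "iteration cap reached"))
  if (n > 0L)
    cat(sprintf("  final c1 = %.3g, c2 = %.3g, nnz(P_Omega S) = %d; lambda = %.4g\n",
                object@trace$c1[n], object@trace$c2[n],
                object@trace$nnz_S_observed[n], object@lambda))
})

setMethod("show", "SubcloneAssignment", function(object) {
  sz <- table(object@labels)
  cat(sprintf("SubcloneAssignment: %d cells in %d subclone(s) [sizes: %s]\n",
              length(object@labels), object@nSubclones,
              paste(as.integer(sz), collapse = ", ")))
})

setMethod("show", "SubcloneTree", function(object) {
  cat(sprintf("SubcloneTree: %d subclone(s), root = subclone %d\n",
              nrow(object@consensus), object@root))
  cat("  ", object@newick, "\n", sep = "")
})

setMethod("show", "SimulatedGenotypes", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SimulatedGenotypes: %d cells x %d sites, %d subclones (FPR=%.2g, FNR=%.2g, MR=%.2g)\n",
    nrow(object@truth), ncol(object@truth), length(object@parent),
    cfg$fpr, cfg$fnr, cfg$mr))
})
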