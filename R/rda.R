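#' Configuration of the robust decomposition
#'
#' @param lambda positive sparsity weight, or \code{"auto"} for the
#'   robust-PCA convention [autoLambda()] (1/sqrt(max(n, m))). The default
#'   0.15 is calibrated for binary genotype matrices: each outer iteration
#'   transfers about \code{lambda} of a corrupted entry's residual into the
#'   sparse part, so 1/lambda iterations clear a flip; larger values make S
#'   sparser.
#' @param epsilon positive convergence tolerance for the Frobenius-ratio
#'   checks c1 and c2.
#' @param maxOuterIters cap on outer iterations.
#' @param binarizeThreshold threshold in (0,1) for calling genotypes from the
#'   recovered matrix (>= wins, so exactly 0.5 calls a mutation).
#' @return a list of class \code{rdaConfig}.
#' @export
rdaConfig <- function(lambda = 0.15, epsilon = 1e-6, maxOuterIters = 30L,
                      binarizeThreshold = 0.5) {
  if (!(identical(lambda, "auto") || (is.numeric(lambda) && lambda > 0)))
    stop("'lambda' must be a positive number or \"auto\"")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (maxOuterIters < 1L) stop("'maxOuterIters' must be >= 1")
  if (binarizeThreshold <= 0 || binarizeThreshold >= 1)
    stop("'binarizeThreshold' must lie in (0,1)")
  structure(list(lambda = lambda, epsilon = epsilon,
                 maxOuterIters = as.integer(maxOuterIters),
                 binarizeThreshold = binarizeThreshold),
            class = "rdaConfig")
}

#' Projection onto the observed-index set
#'
#' Keeps observed entries and zeroes the rest: the entrywise product of
#' \code{M} with the binary mask of Omega.
#'
#' @param M n x m numeric matrix.
#' @param omegaMask n x m matrix in \{0,1\}; 1 marks an observed entry.
#' @return n x m numeric matrix.
#' @export
projectOmega <- function(M, omegaMask) {
  if (!identical(dim(M), dim(omegaMask)))
    stop("dimension mismatch between matrix and mask")
  M * omegaMask
}

#' Elementwise soft-thresholding of the sparse part on observed entries
#'
#' The proximal operator of the l1 penalty restricted to Omega:
#' observed entries become \code{sign(s) * max(|s| - lambda, 0)}; entries
#' outside Omega carry the imputation residual, are unpenalized, and are
#' returned unchanged.
#'
#' @param S n x m numeric matrix.
#' @param lambda positive shrinkage amount.
#' @param omegaMask n x m matrix in \{0,1\}; 1 marks an observed entry.
#' @return n x m numeric matrix.
#' @export
softShrink <- function(S, lambda, omegaMask) {
  if (!is.numeric(lambda) || lambda <= 0) stop("'lambda' must be positive")
  if (!identical(dim(S), dim(omegaMask)))
    stop("dimension mismatch between matrix and mask")
  Sobs <- S * omegaMask
  S * (1 - omegaMask) + sign(Sobs) * pmax(abs(Sobs) - lambda, 0)
}

#' Default sparsity weight of robust decompositions
#'
#' The robust-PCA convention 1/sqrt(max(n, m)), used when the configuration
#' requests \code{lambda = "auto"}.
#'
#' @param n,m matrix dimensions.
#' @return positive scalar.
#' @examples
#' autoLambda(100, 100)  # 0.1
#' @export
autoLambda <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  1 / sqrt(max(n, m))
}

#' Binarize a recovered matrix into genotype calls
#'
#' @param LD n x m numeric matrix.
#' @param threshold calling threshold in (0,1); entries >= threshold become 1.
#' @return n x m integer matrix in \{0,1\}.
#' @export
binarizeGenotypes <- function(LD, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must lie in (0,1)")
  calls <- (LD >= threshold) * 1L
  storage.mode(calls) <- "integer"
  calls
}

#' Extended robust deep autoencoder decomposition
#'
#' Decomposes an observed genotype matrix into a low-rank recovered matrix LD
#' (the autoencoder reconstruction) and a sparse error matrix S, alternating
#' \enumerate{
#'   \item \code{LD <- X - S}
#'   \item refit the autoencoder parameters on the rows of LD and replace LD
#'     by its reconstruction
#'   \item \code{S <- X - LD}, then soft-threshold S on observed entries only
#' }
#' and stopping when either Frobenius-ratio check
#' \code{c1 = ||X - LD - S|| / ||X||} (constraint violation) or
#' \code{c2 = ||LD_prev - LD|| / ||X||} (iterate change of the recovered
#' matrix) drops below \code{epsilon}, or the iteration cap is reached.
#' Because the l1 penalty is restricted to observed entries, missing entries
#' flow through LD and are imputed by the low-rank structure; LD + S = X
#' holds exactly on unobserved entries at every iteration. LD is finally
#' binarized into genotype calls.
#'
#' @param x a [GenotypeMatrix-class], or an n x m numeric matrix zero-filled
#'   at unobserved entries (as produced by [encodeForRDA()]).
#' @param omegaMask for the matrix method: n x m \{0,1\} mask of observed
#'   entries; defaults to all-ones (fully observed).
#' @param config an [rdaConfig()].
#' @param spec an [autoencoderSpec()].
#' @param ... passed between methods.
#' @return an [RDADecomposition-class].
#' @examples
#' sim <- simulateDataset(simulationConfig(60, 40, 3, fpr = 0, fnr = 0, mr = 0,
#'                                         seed = 1))
#' dec <- rdaDecompose(observedMatrix(sim))
#' all(genotypeCalls(dec) == truthMatrix(sim))
#' @export
setGeneric("rdaDecompose",
           function(x, ..., config = rdaConfig(), spec = autoencoderSpec())
             standardGeneric("rdaDecompose"))

#' @rdname rdaDecompose
#' @export
setMethod("rdaDecompose", "GenotypeMatrix",
  function(x, ..., config = rdaConfig(), spec = autoencoderSpec()) {
    enc <- encodeForRDA(x)
    .rdaDecomposeMatrix(enc$X, enc$omegaMask, config, spec)
  })

#' @rdname rdaDecompose
#' @export
setMethod("rdaDecompose", "matrix",
  function(x, omegaMask = NULL, ..., config = rdaConfig(), spec = autoencoderSpec()) {
    if (is.null(omegaMask)) omegaMask <- matrix(1, nrow(x), ncol(x))
    .rdaDecomposeMatrix(x, omegaMask, config, spec)
  })

.rdaDecomposeMatrix <- function(X, omegaMask, config, spec) {
    if (!identical(dim(X), dim(omegaMask)))
      stop("dimension mismatch between matrix and mask")
    normX <- sqrt(sum(X^2))
    if (normX == 0) stop("degenerate input: ||X|| = 0 (no observed mutations)")
    lambda <- if (identical(config$lambda, "auto"))
      autoLambda(nrow(X), ncol(X)) else config$lambda

    state <- .aeInit(ncol(X), spec)
    LD <- X * 0; S <- X * 0; LS <- X
    LDprev <- LD
    trace <- vector("list", config$maxOuterIters)
    converged <- FALSE
    it <- 0L
    while (it < config$maxOuterIters) {
      it <- it + 1L
      LD <- X - S
      fit <- refitAutoencoder(state, LD, spec, iteration = it)
      state <- fit$state
      LD <- fit$LDhat
      S <- softShrink(X - LD, lambda, omegaMask)
      c1 <- sqrt(sum((X - LD - S)^2)) / normX
      # iterate-change check on the recovered matrix itself: the textbook
      # form ||LS - LD - S|| is identically zero whenever every observed
      # residual exceeds lambda with a stable sign (LD + S is then pinned at
      # X - lambda * sign(residual) even while LD still moves), which stalls
      # the loop long before the reconstruction has converged
      c2 <- sqrt(sum((LDprev - LD)^2)) / normX
      trace[[it]] <- data.frame(
        iteration = it, c1 = c1, c2 = c2,
        nnz_S_observed = sum(S != 0 & omegaMask == 1))
      if (c1 < config$epsilon || c2 < config$epsilon) { converged <- TRUE; break }
      LS <- LD + S
      LDprev <- LD
    }
    if (!converged)
      warning(sprintf(
        "iteration cap (%d) reached before c1/c2 < %.2g; returning last iterate",
        config$maxOuterIters, config$epsilon))
    calls <- binarizeGenotypes(LD, config$binarizeThreshold)
    new("RDADecomposition", LD = LD, S = S, LS = LS,
        trace = do.call(rbind, trace[seq_len(it)]),
        genotypeCalls = calls, converged = converged, iterationsRun = it,
        lambda = lambda, threshold = config$binarizeThreshold)
}
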