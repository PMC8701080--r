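## Dense symmetric autoencoder with Adam, written directly on BLAS matmuls.
## Rows of the input are the training samples (one per cell). Kept internal
## except for the refit entry point the decomposition loop calls.

.relu <- function(x) (x > 0) * x
.sigmoid <- function(x) 1 / (1 + exp(-x))

.defaultWidths <- function(m) {
  unique(pmin(c(128L, max(8L, ceiling(m / 8))), m))
}

#' Autoencoder architecture and training hyperparameters
#'
#' The encoder maps a cell's m-site genotype row through fully connected
#' hidden layers of the given widths (the last width is the bottleneck); the
#' decoder mirrors the encoder back to m outputs. With the default sigmoid
#' output the reconstruction is a per-entry mutation probability and the
#' refit minimizes the Bernoulli cross-entropy; with a linear output it
#' minimizes the squared loss.
#'
#' @param encoderWidths integer vector of hidden widths ending in the
#'   bottleneck; \code{NULL} (default) derives \code{c(min(128, m),
#'   max(8, ceiling(m/8)))} from the data at fit time.
#' @param activation hidden activation, \code{"relu"} or \code{"tanh"}.
#' @param outputActivation \code{"sigmoid"} (default; genotypes live in
#'   [0,1]) or \code{"linear"}.
#' @param innerEpochs passes of stochastic refit per outer iteration.
#' @param batchCells cells per stochastic mini-batch (clamped to n).
#' @param learningRate Adam step size.
#' @param seed integer seed for weight initialization and batch order.
#' @return a list of class \code{autoencoderSpec}.
#' @export
autoencoderSpec <- function(encoderWidths = NULL, activation = c("relu", "tanh"),
                            outputActivation = c("sigmoid", "linear"),
                            innerEpochs = 10L, batchCells = 256L,
                            learningRate = 3e-3, seed = 1L) {
  activation <- match.arg(activation)
  outputActivation <- match.arg(outputActivation)
  if (!is.null(encoderWidths)) {
    encoderWidths <- as.integer(encoderWidths)
    if (length(encoderWidths) < 1L || any(encoderWidths < 1L))
      stop("'encoderWidths' must be positive integers")
  }
  if (innerEpochs < 1L) stop("'innerEpochs' must be >= 1")
  if (batchCells < 1L) stop("'batchCells' must be >= 1")
  if (learningRate <= 0) stop("'learningRate' must be positive")
  structure(list(encoderWidths = encoderWidths, activation = activation,
                 outputActivation = outputActivation,
                 innerEpochs = as.integer(innerEpochs),
                 batchCells = as.integer(batchCells),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "autoencoderSpec")
}

# He-style initialization; dims = c(m, widths..., rev(widths)[-1]..., m)
.aeInit <- function(m, spec) {
  widths <- spec$encoderWidths
  if (is.null(widths)) widths <- .defaultWidths(m)
  widths <- pmin(widths, m)
  if (widths[length(widths)] >= m && m > 1L)
    widths[length(widths)] <- m - 1L  # bottleneck must compress
  dims <- c(m, widths, rev(widths)[-1L], m)
  set.seed(spec$seed %% .Machine$integer.max)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  zW <- lapply(W, function(w) w * 0)
  zb <- lapply(b, function(x) x * 0)
  list(W = W, b = b, mW = zW, vW = zW, mb = zb, vb = zb, t = 0L, dims = dims)
}

.aeForward <- function(state, X, spec) {
  L <- length(state$W); A <- X
  act <- spec$activation
  for (l in seq_len(L)) {
    A <- sweep(A %*% state$W[[l]], 2L, state$b[[l]], "+")
    A <- if (l < L) {
      if (act == "relu") .relu(A) else tanh(A)
    } else if (spec$outputActivation == "sigmoid") .sigmoid(A) else A
  }
  A
}

.aeLoss <- function(state, X, spec) {
  Y <- .aeForward(state, X, spec)
  if (spec$outputActivation == "sigmoid") {
    T_ <- pmin(pmax(X, 0), 1)
    Yc <- pmin(pmax(Y, 1e-12), 1 - 1e-12)
    -mean(T_ * log(Yc) + (1 - T_) * log(1 - Yc))
  } else {
    mean((Y - X)^2)
  }
}

# One Adam update on a mini-batch; returns the updated state.
.aeStep <- function(state, batch, spec) {
  L <- length(state$W)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- spec$learningRate
  A <- vector("list", L + 1L); A[[1L]] <- batch
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% state$W[[l]], 2L, state$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) {
      if (spec$activation == "relu") .relu(Z) else tanh(Z)
    } else if (spec$outputActivation == "sigmoid") .sigmoid(Z) else Z
  }
  # output-layer gradient: (A - target) for sigmoid/cross-entropy,
  # 2 (A - target) A'(..) collapses to the same expression up to the factor 2
  # for linear/MSE; both scaled by batch size
  d <- (A[[L + 1L]] - batch) / nrow(batch)
  if (!all(is.finite(d)))
    stop("non-finite reconstruction loss; consider lowering learningRate")
  state$t <- state$t + 1L
  cor1 <- 1 - b1^state$t; cor2 <- 1 - b2^state$t
  for (l in rev(seq_len(L))) {
    gW <- crossprod(A[[l]], d)
    gb <- colSums(d)
    if (l > 1L) {
      d <- d %*% t(state$W[[l]])
      d <- if (spec$activation == "relu") d * (A[[l]] > 0) else d * (1 - A[[l]]^2)
    }
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * gW
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * gW^2
    state$W[[l]] <- state$W[[l]] -
      lr * (state$mW[[l]] / cor1) / (sqrt(state$vW[[l]] / cor2) + eps)
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * gb
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * gb^2
    state$b[[l]] <- state$b[[l]] -
      lr * (state$mb[[l]] / cor1) / (sqrt(state$vb[[l]] / cor2) + eps)
  }
  state
}

#' Refit the autoencoder on the current low-rank iterate
#'
#' Runs \code{innerEpochs} passes of stochastic gradient refit of the
#' reconstruction loss on mini-batches of \code{batchCells} rows,
#' warm-starting from the incoming parameters, then reconstructs every row
#' under the updated parameters. Deterministic given \code{(spec$seed,
#' iteration)}.
#'
#' @param state autoencoder state from a previous call, or \code{NULL} to
#'   initialize fresh parameters for \code{ncol(LD)} inputs.
#' @param LD n x m numeric matrix; rows are the training samples.
#' @param spec an [autoencoderSpec()].
#' @param iteration outer-iteration index used to derive the batch-order seed.
#' @return list with \code{state} (updated parameters) and \code{LDhat}
#'   (the n x m reconstruction of \code{LD}).
#' @export
refitAutoencoder <- function(state, LD, spec = autoencoderSpec(), iteration = 1L) {
  LD <- as.matrix(LD)
  n <- nrow(LD)
  if (is.null(state)) state <- .aeInit(ncol(LD), spec)
  batch <- min(spec$batchCells, n)
  set.seed((spec$seed + 7919L * as.integer(iteration)) %% .Machine$integer.max)
  for (ep in seq_len(spec$innerEpochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      state <- .aeStep(state, LD[idx, , drop = FALSE], spec)
    }
  }
  list(state = state, LDhat = .aeForward(state, LD, spec))
}
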