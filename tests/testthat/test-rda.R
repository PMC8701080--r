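test_that("projectOmega keeps observed entries and is idempotent", {
  M <- rbind(c(1, 0.5), c(0.2, 1))
  mask <- rbind(c(1, 0), c(0, 1))
  expect_equal(projectOmega(M, mask), rbind(c(1, 0), c(0, 1)))
  expect_equal(projectOmega(M, matrix(1, 2, 2)), M)
  expect_equal(projectOmega(projectOmega(M, mask), mask), projectOmega(M, mask))
  expect_error(projectOmega(M, matrix(1, 3, 2)), "dimension mismatch")
})

test_that("softShrink is the masked l1 proximal operator", {
  one <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  expect_equal(softShrink(matrix(0.8), 0.3, one), matrix(0.5))
  expect_equal(softShrink(matrix(-0.2), 0.3, one), matrix(0))
  expect_equal(softShrink(matrix(-0.7), 0.3, zero), matrix(-0.7))
  expect_error(softShrink(matrix(1), -1, one), "positive")

  # closed form on many random scalars
  set.seed(1)
  s <- matrix(runif(1e4, -2, 2), 100, 100)
  lam <- 0.37
  expect_equal(softShrink(s, lam, matrix(1, 100, 100)),
               sign(s) * pmax(abs(s) - lam, 0), tolerance = 1e-12)

  # grid-search minimizer of (1/2)(x - s)^2 + lam |x|
  grid <- seq(-3, 3, by = 1e-4)
  set.seed(2)
  for (s1 in runif(100, -2, 2)) {
    best <- grid[which.min(0.5 * (grid - s1)^2 + lam * abs(grid))]
    expect_lt(abs(softShrink(matrix(s1), lam, one)[1, 1] - best), 1e-3)
  }
})

test_that("autoLambda follows the robust-PCA convention", {
  expect_equal(autoLambda(100, 100), 0.1)
  expect_equal(autoLambda(3000, 1000), 1 / sqrt(3000))
  sizes <- c(10, 50, 100, 500, 3000)
  expect_true(all(diff(vapply(sizes, function(n) autoLambda(n, 10), 0)) <= 0))
})

test_that("binarizeGenotypes thresholds with the >= tie rule", {
  LD <- matrix(c(0.7, 0.5, -0.1, 0.49), 2, 2)
  expect_equal(unname(binarizeGenotypes(LD, 0.5)), matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_error(binarizeGenotypes(LD, 0), "\\(0,1\\)")
})

test_that("autoencoder refit makes training progress and reconstructs rank-1 data", {
  set.seed(42)
  row <- rbinom(30, 1, 0.4)
  LD <- matrix(rep(row, each = 40), 40, 30)

  # refit does not increase the reconstruction loss (averaged over seeds)
  deltas <- vapply(1:3, function(s) {
    spec <- autoencoderSpec(seed = s)
    st0 <- subcloneRDA:::.aeInit(ncol(LD), spec)
    before <- subcloneRDA:::.aeLoss(st0, LD, spec)
    after <- subcloneRDA:::.aeLoss(refitAutoencoder(st0, LD, spec, 1L)$state, LD, spec)
    after - before
  }, 0)
  expect_lt(mean(deltas), 0)

  # rank-1 input is representable: over the default outer budget of
  # warm-started refits the per-entry error collapses
  spec <- autoencoderSpec(seed = 3)
  st <- NULL
  for (it in seq_len(rdaConfig()$maxOuterIters)) {
    f <- refitAutoencoder(st, LD, spec, iteration = it)
    st <- f$state
  }
  expect_lt(max(abs(f$LDhat - LD)), 0.05)
  expect_equal(dim(f$LDhat), dim(LD))
})

test_that("clean clone-structured input is a fixed point of the decomposition", {
  X <- rbind(matrix(rep(c(rep(1, 5), rep(0, 5)), each = 10), 10, 10),
             matrix(rep(c(rep(0, 5), rep(1, 5)), each = 10), 10, 10))
  # exact calls at the default budget for every seed; the sparse part is
  # empty up to a handful of slowly saturating entries
  for (s in 1:3) {
    dec <- quietDecompose(X, spec = autoencoderSpec(seed = s))
    expect_true(all(genotypeCalls(dec) == X))
    expect_lte(mean(sparseMatrixPart(dec) != 0), 0.05)
    expect_lte(max(abs(sparseMatrixPart(dec))), 0.35)
    tr <- convergenceTrace(dec)
    expect_gt(nrow(tr), 0L)
    if (dec@converged)
      expect_lt(min(tr$c1[nrow(tr)], tr$c2[nrow(tr)]), rdaConfig()$epsilon)
  }
  # with a doubled iteration budget the fixed point is exact: S vanishes
  dec60 <- quietDecompose(X, config = rdaConfig(maxOuterIters = 60))
  expect_true(all(genotypeCalls(dec60) == X))
  expect_true(all(sparseMatrixPart(dec60) == 0))
})

test_that("masked entries of a clean low-rank matrix are imputed", {
  X <- rbind(matrix(rep(c(rep(1, 5), rep(0, 5)), each = 10), 10, 10),
             matrix(rep(c(rep(0, 5), rep(1, 5)), each = 10), 10, 10))
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    mask <- matrix(as.numeric(runif(200) > 0.3), 20, 10)
    dec <- quietDecompose(X * mask, omegaMask = mask,
                          spec = autoencoderSpec(seed = s))
    mean(genotypeCalls(dec)[mask == 0] == X[mask == 0])
  }, 0)
  expect_gte(mean(accs), 0.95)
})

test_that("the constraint LD + S = X holds exactly off omega at every iteration", {
  sim <- simulateDataset(simulationConfig(60, 40, 4, fpr = 0.1, fnr = 0.1,
                                          mr = 0.3, seed = 9))
  enc <- encodeForRDA(observedMatrix(sim))
  for (cap in c(1L, 2L, 3L)) {
    dec <- quietDecompose(enc$X, omegaMask = enc$omegaMask,
                          config = rdaConfig(maxOuterIters = cap))
    resid <- enc$X - recoveredMatrix(dec) - sparseMatrixPart(dec)
    expect_identical(unique(resid[enc$omegaMask == 0]), 0)
    # on omega the residual is exactly what shrinkage removed (|.| <= lambda)
    expect_lte(max(abs(resid[enc$omegaMask == 1])), dec@lambda + 1e-12)
    # c1 of the last trace row matches the returned matrices
    tr <- convergenceTrace(dec)
    expect_equal(tr$c1[nrow(tr)], sqrt(sum(resid^2)) / sqrt(sum(enc$X^2)))
  }
})

test_that("sparsity of S is monotone in lambda and runs are bit-reproducible", {
  sim <- simulateDataset(simulationConfig(80, 50, 4, fpr = 0.15, fnr = 0.15,
                                          mr = 0.2, seed = 21))
  enc <- encodeForRDA(observedMatrix(sim))
  nnz <- vapply(c(0.01, 0.05, 0.1, 0.5), function(lam) {
    dec <- quietDecompose(enc$X, omegaMask = enc$omegaMask,
                          config = rdaConfig(lambda = lam),
                          spec = autoencoderSpec(seed = 7))
    tr <- convergenceTrace(dec)
    tr$nnz_S_observed[nrow(tr)]
  }, 0)
  expect_true(all(diff(nnz) <= 0))

  d1 <- quietDecompose(observedMatrix(sim), spec = autoencoderSpec(seed = 5))
  d2 <- quietDecompose(observedMatrix(sim), spec = autoencoderSpec(seed = 5))
  expect_identical(convergenceTrace(d1), convergenceTrace(d2))
  expect_identical(genotypeCalls(d1), genotypeCalls(d2))
  expect_identical(recoveredMatrix(d1), recoveredMatrix(d2))
})

test_that("degenerate and invalid decomposition inputs are rejected", {
  expect_error(rdaDecompose(matrix(0, 4, 4)), "degenerate")
  expect_error(rdaDecompose(matrix(1, 4, 4), omegaMask = matrix(1, 2, 2)),
               "dimension mismatch")
  expect_error(rdaConfig(lambda = -1), "positive")
  expect_error(rdaConfig(binarizeThreshold = 1.2), "\\(0,1\\)")
  # lambda = "auto" resolves to the convention
  X <- rbind(matrix(rep(c(1, 1, 0, 0), each = 6), 6, 4),
             matrix(rep(c(0, 0, 1, 1), each = 6), 6, 4))
  dec <- quietDecompose(X, config = rdaConfig(lambda = "auto", maxOuterIters = 2))
  expect_equal(dec@lambda, 1 / sqrt(12))
})
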