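test_that("reader parses sentinels, labels and both orientations", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("1,3", "0,1"), p)
  g <- readGenotypeMatrix(p)
  expect_equal(unname(genotypeValues(g)), rbind(c(1, NA), c(0, 1)))
  expect_equal(sum(!is.na(genotypeValues(g))), 3L)

  writeLines(c("0,0", "0,0", "0,0"), p)
  g <- readGenotypeMatrix(p)
  expect_equal(dim(g), c(3L, 2L))
  expect_true(all(genotypeValues(g) == 0))
  expect_equal(sum(!is.na(genotypeValues(g))), 6L)

  # header + row labels, tab-separated, sites-as-rows normalized to cells-as-rows
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("site\tcA\tcB\tcC", "s1\t1\t0\t1", "s2\t3\t1\t0"), p2)
  g2 <- readGenotypeMatrix(p2, orientation = "sites_as_rows")
  expect_equal(cellIds(g2), c("cA", "cB", "cC"))
  expect_equal(siteIds(g2), c("s1", "s2"))
  expect_equal(unname(genotypeValues(g2)),
               rbind(c(1, NA), c(0, 1), c(1, 0)))
})

test_that("reader rejects ragged tables, bad tokens and all-missing input", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("1,0", "0"), p)
  expect_error(readGenotypeMatrix(p), "ragged.*line 2")
  writeLines(c("1,0", "0,2"), p)
  expect_error(readGenotypeMatrix(p), "invalid token '2' at data row 2, column 2")
  writeLines(c("3,3", "3,3"), p)
  expect_error(readGenotypeMatrix(p), "every entry is missing")
})

test_that("write-then-read is the identity on values, omega and labels", {
  set.seed(11)
  for (rep_ in 1:5) {
    v <- matrix(sample(c(0, 1, NA), 6 * 4, replace = TRUE), 6, 4)
    if (all(is.na(v))) v[1, 1] <- 1
    g <- genotypeMatrix(v, cellIds = paste0("c", 1:6), siteIds = paste0("s", 1:4))
    p <- tempfile(fileext = ".tsv")
    writeGenotypeMatrix(g, p)
    g2 <- readGenotypeMatrix(p)
    expect_identical(genotypeValues(g2), genotypeValues(g))
    expect_identical(cellIds(g2), cellIds(g))
    expect_identical(siteIds(g2), siteIds(g))
  }
})

test_that("encodeForRDA implements the projection onto omega", {
  g <- genotypeMatrix(rbind(c(1, NA), c(0, 1)))
  enc <- encodeForRDA(g)
  expect_equal(unname(enc$X), rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(enc$omegaMask), rbind(c(1, 0), c(1, 1)))

  full <- genotypeMatrix(rbind(c(1, 0), c(0, 1)))
  encF <- encodeForRDA(full)
  expect_equal(unname(encF$X), unname(genotypeValues(full)))
  expect_true(all(encF$omegaMask == 1))

  # fully missing row: zero-filled values, zero mask
  gm <- genotypeMatrix(rbind(c(NA, NA), c(0, 1)))
  encM <- encodeForRDA(gm)
  expect_true(all(encM$X[1, ] == 0) && all(encM$omegaMask[1, ] == 0))

  # mask sums to |omega|; observed values never change
  set.seed(5)
  v <- matrix(sample(c(0, 1, NA), 40, replace = TRUE), 8, 5)
  g3 <- genotypeMatrix(v)
  enc3 <- encodeForRDA(g3)
  expect_equal(sum(enc3$omegaMask), sum(!is.na(v)))
  expect_equal(enc3$X[!is.na(v)], v[!is.na(v)])
})

test_that("writeOutputs orders cells by label and handles one-subclone trees", {
  calls <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 0L))
  g <- genotypeMatrix(calls, cellIds = paste0("cell", 0:3))
  dec <- new("RDADecomposition", LD = calls * 1.0, S = calls * 0, LS = calls * 1.0,
             trace = data.frame(iteration = 1L, c1 = 0, c2 = 0, nnz_S_observed = 0L),
             genotypeCalls = calls, converged = TRUE, iterationsRun = 1L,
             lambda = 0.15, threshold = 0.5)
  asg <- new("SubcloneAssignment", labels = c(1L, 0L, 1L, 0L), nSubclones = 2L)
  tree <- buildSubcloneTree(calls, asg)
  d <- tempfile()
  writeOutputs(list(genotypes = g, decomposition = dec, assignment = asg,
                    tree = tree, metrics = list(ari = 1)), d)
  rec <- read.delim(file.path(d, "recovered.tsv"), row.names = 1)
  # label-0 block first (cells 1 and 3 in 0-based ids), stable within block
  expect_equal(rownames(rec), c("cell1", "cell3", "cell0", "cell2"))

  # degenerate single-subclone run: header-only edges, lone leaf in Newick
  asg1 <- new("SubcloneAssignment", labels = rep(0L, 4L), nSubclones = 1L)
  tree1 <- buildSubcloneTree(calls, asg1)
  d1 <- tempfile()
  writeOutputs(list(genotypes = g, decomposition = dec, assignment = asg1,
                    tree = tree1, metrics = NULL), d1)
  edges <- read.delim(file.path(d1, "tree_edges.tsv"))
  expect_equal(nrow(edges), 0L)
  expect_equal(names(edges), c("parent", "child", "weight"))
  expect_equal(readLines(file.path(d1, "tree.nwk")), "subclone_0;")
})

test_that("metrics.json keys match the evaluation report fields", {
  sim <- simulateDataset(simulationConfig(40, 25, 3, fpr = 0.1, fnr = 0.1,
                                          mr = 0.2, seed = 4))
  d <- tempfile()
  run <- quietPipeline(sim, outdir = d, seed = 4)
  written <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_setequal(names(written), names(run$metrics))
  expect_setequal(names(written),
                  c("fpnr_recovered", "fpnr_input", "fpnr_ratio",
                    "missing_accuracy", "error", "precision", "recall", "f1",
                    "TP", "FP", "TN", "FN", "ari", "nmi", "v_measure"))
})

test_that("missingDialect validates its tokens", {
  expect_error(missingDialect(character(0)), "non-empty")
  expect_error(missingDialect(c("3", "NA"), writeToken = "?"), "one of the sentinels")
  d <- missingDialect(c("?", "NA"), "?")
  g <- genotypeMatrix(rbind(c(1, NA), c(0, 1)))
  p <- tempfile(fileext = ".tsv")
  writeGenotypeMatrix(g, p, dialect = d)
  expect_match(readLines(p)[2], "\\?")
  expect_identical(genotypeValues(readGenotypeMatrix(p, dialect = d)),
                   genotypeValues(g))
})
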