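test_that("kNN neighbor sets match an exhaustive pairwise-distance sort", {
  set.seed(31)
  G <- matrix(rnorm(30 * 6), 30, 6)   # continuous rows: no distance ties
  k <- 4L
  nb <- knnNeighbors(G, k)
  D <- as.matrix(dist(G))
  for (i in seq_len(30)) {
    expected <- setdiff(order(D[i, ]), i)[seq_len(k)]
    expect_identical(nb[[i]], expected)
  }
})

test_that("kNN ties break to the lower index and k is clamped", {
  # two identical pairs: each cell's single neighbor is its twin
  G <- rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  nb <- knnNeighbors(G, 1L)
  expect_equal(unlist(nb), c(3L, 4L, 1L, 2L))

  # all cells identical: neighbors are the lowest-index other cells
  G2 <- matrix(1, 5, 3)
  nb2 <- knnNeighbors(G2, 2L)
  expect_equal(nb2[[1L]], c(2L, 3L))
  expect_equal(nb2[[4L]], c(1L, 2L))

  expect_warning(knnNeighbors(G2, 10L), "clamped")
})

test_that("Jaccard weights follow |intersection| / |union|", {
  # hand-built neighbor sets over 8 cells; pairs qualify when one cell lists
  # the other as a neighbor
  nb <- list(c(2L, 3L),      # 1: {2,3} vs N(2)={3,4} -> |n|=1, |u|=3 -> 1/3
             c(3L, 4L),      # 2
             c(1L, 2L),      # 3
             c(2L, 5L),      # 4
             c(4L, 2L),      # 5: with 4 shares {2}, union {2,4,5} -> 1/3
             c(7L, 8L),      # 6: N(7)={8,6}: shares {8}; vs pair (6,7)
             c(8L, 6L),      # 7
             c(1L, 2L))      # 8: N(6) n N(8) = emptyset -> edge dropped
  ed <- jaccardEdges(nb)
  key <- paste(ed$from, ed$to)
  expect_equal(ed$weight[key == "1 2"], 1 / 3)
  # maximal overlap among qualifying pairs: N(4)={2,5}, N(5)={4,2}
  # intersection {2}, union {2,4,5} -> 1/3
  expect_equal(ed$weight[key == "4 5"], 1 / 3)
  expect_false("6 8" %in% key)   # disjoint neighbor sets are dropped
  # every reported weight matches a direct set computation
  for (r in seq_len(nrow(ed))) {
    i <- ed$from[r]; j <- ed$to[r]
    expect_equal(ed$weight[r],
                 length(intersect(nb[[i]], nb[[j]])) /
                   length(union(nb[[i]], nb[[j]])))
    expect_true(j %in% nb[[i]] || i %in% nb[[j]])
  }
})

test_that("Louvain recovers planted communities and renumbers by size", {
  # two 10-cliques joined by one light edge
  cl1 <- t(combn(1:10, 2)); cl2 <- t(combn(11:20, 2))
  edges <- data.frame(from = c(cl1[, 1], cl2[, 1], 1L),
                      to = c(cl1[, 2], cl2[, 2], 11L),
                      weight = c(rep(1, nrow(cl1) + nrow(cl2)), 0.01))
  asg <- louvainCluster(edges, 20L, clusterConfig(seed = 1))
  expect_equal(nSubclones(asg), 2L)
  expect_equal(length(unique(subcloneLabels(asg)[1:10])), 1L)
  expect_equal(length(unique(subcloneLabels(asg)[11:20])), 1L)

  # fully connected uniform graph has no community structure
  full <- t(combn(1:8, 2))
  asgF <- louvainCluster(data.frame(from = full[, 1], to = full[, 2], weight = 1),
                         8L, clusterConfig(seed = 1))
  expect_equal(nSubclones(asgF), 1L)

  # largest cluster gets label 0
  cl3 <- t(combn(1:12, 2)); cl4 <- t(combn(13:17, 2))
  edges2 <- data.frame(from = c(cl3[, 1], cl4[, 1]), to = c(cl3[, 2], cl4[, 2]),
                       weight = 1)
  asg2 <- louvainCluster(edges2, 17L, clusterConfig(seed = 1))
  expect_true(all(subcloneLabels(asg2)[1:12] == 0L))

  expect_warning(
    louvainCluster(data.frame(from = integer(0), to = integer(0),
                              weight = numeric(0)), 3L),
    "empty edge list")
})

test_that("clustering is equivariant under cell permutation on clone data", {
  fx <- makePathCloneMatrix(K = 4, cellsPerClone = 8, sitesPerStep = 5)
  cfg <- clusterConfig(kNeighbors = 5, seed = 2)
  a1 <- clusterSubclones(fx$calls, cfg)
  set.seed(17)
  perm <- sample.int(nrow(fx$calls))
  a2 <- clusterSubclones(fx$calls[perm, ], cfg)
  expect_equal(adjustedRandIndex(subcloneLabels(a1)[perm], subcloneLabels(a2)), 1)
})

test_that("small clusters can be merged into their nearest neighbor", {
  calls <- rbind(matrix(0, 10, 6), matrix(1, 10, 6),
                 cbind(matrix(1, 2, 3), matrix(0, 2, 3)))
  asg <- clusterSubclones(calls, clusterConfig(kNeighbors = 3, seed = 1,
                                               minClusterSize = 5))
  expect_lte(nSubclones(asg), 2L)
  expect_true(all(table(subcloneLabels(asg)) >= 5))
})

test_that("clustering accuracy is robust to the Louvain resolution", {
  # default-noise clone data; the recovered matrix is clustered at three
  # resolutions and the mean ARI to truth may move by < 0.05
  ari <- matrix(NA_real_, 3, 3, dimnames = list(NULL, c("0.5", "1", "1.5")))
  for (s in 1:3) {
    sim <- simulateDataset(simulationConfig(300, 200, 10, seed = 100 + s))
    dec <- quietDecompose(observedMatrix(sim), spec = autoencoderSpec(seed = s))
    for (r in c(0.5, 1, 1.5)) {
      asg <- clusterSubclones(genotypeCalls(dec),
                              clusterConfig(resolution = r, seed = s))
      ari[s, as.character(r)] <- adjustedRandIndex(subcloneLabels(asg),
                                                   trueLabels(sim))
    }
  }
  means <- colMeans(ari)
  expect_lt(max(means) - min(means), 0.05)
})
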