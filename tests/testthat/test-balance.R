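test_that("DANGER membership matches the brute-force k-NN oracle", {
  toy <- borderToy()
  expect_identical(dangerSet(toy$X, toy$y, "min", m = 5),
                   bruteDangerSet(toy$X, toy$y, "min", 5L))
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
    y <- sample(c("min", "maj"), 20, TRUE, prob = c(0.3, 0.7))
    if (sum(y == "min") < 2) next
    expect_identical(dangerSet(X, y, "min", m = 5),
                     bruteDangerSet(X, y, "min", 5L))
  }
})

test_that("borderline-SMOTE synthesizes exactly on parent segments", {
  toy <- borderToy()
  plan <- balancingPlan(c(min = 9L, maj = 4L), seed = 5)
  syn <- borderlineSmote(toy$X, toy$y, "min", 7L, plan)
  expect_identical(nrow(syn@features), 7L)
  expect_true(all(syn@u >= 0 & syn@u <= 1))
  for (s in seq_len(7)) {
    expected <- toy$X[syn@parentA[s], ] +
      syn@u[s] * (toy$X[syn@parentB[s], ] - toy$X[syn@parentA[s], ])
    expect_identical(unname(syn@features[s, ]), unname(expected))
  }
  expect_true(all(syn@classLabel == "min"))
  expect_true(all(toy$y[syn@parentA] == "min"))
  expect_true(all(toy$y[syn@parentB] == "min"))
  # determinism
  syn2 <- borderlineSmote(toy$X, toy$y, "min", 7L, plan)
  expect_identical(syn@features, syn2@features)
  # single-member minority is an error
  expect_error(borderlineSmote(toy$X[-1, ], toy$y[-1], "min", 3L, plan), "< 2 members")
})

test_that("SMOTE falls back to all minority points when no sample is borderline", {
  # minority cluster far from the majority: DANGER is empty
  X <- rbind(matrix(rnorm(10, sd = 0.1), ncol = 2),
             matrix(rnorm(20, mean = 50, sd = 0.1), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- c(rep("min", 5), rep("maj", 10))
  expect_length(dangerSet(X, y, "min", 5), 0)
  expect_message(syn <- borderlineSmote(X, y, "min", 4L, balancingPlan(c(min = 9L, maj = 10L))),
                 "classic SMOTE")
  expect_identical(nrow(syn@features), 4L)
})

test_that("ADASYN allocates the deficit by difficulty with residue policy", {
  toy <- adasynToy()
  plan <- balancingPlan(c(min = 14L, maj = 16L), seed = 3)
  syn <- adasyn(toy$X, toy$y, "min", 6L, plan)
  expect_identical(nrow(syn@features), 6L)
  alloc <- attr(syn, "allocation")
  # difficulty ratios are (1, 0.2, 0, ...): round(6 * r / 1.2) = (5, 1, 0, ...)
  expect_identical(unname(alloc), c(5, 1, 0, 0, 0, 0, 0, 0))
  # geometry exactness
  for (s in seq_len(6)) {
    expected <- toy$X[syn@parentA[s], ] +
      syn@u[s] * (toy$X[syn@parentB[s], ] - toy$X[syn@parentA[s], ])
    expect_identical(unname(syn@features[s, ]), unname(expected))
  }
})

test_that("ADASYN falls back to a uniform allocation when all ratios are zero", {
  X <- rbind(matrix(rnorm(12, sd = 0.05), ncol = 2),
             matrix(rnorm(24, mean = 40, sd = 0.05), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- c(rep("min", 6), rep("maj", 12))
  expect_message(syn <- adasyn(X, y, "min", 7L, balancingPlan(c(min = 13L, maj = 12L))),
                 "uniform")
  expect_identical(nrow(syn@features), 7L)
})

test_that("uncertainty filtering retains confident samples and is deterministic", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(60, mean = 6, sd = 0.3), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 30)
  plan <- balancingPlan(c(a = 35L, b = 30L), seed = 9)
  syn <- borderlineSmote(X, y, "a", 5L, plan)

  # tau = Inf with the vote check off retains everything
  all1 <- uncertaintyFilter(X, y, syn, tau = Inf, majorityCheck = FALSE, seed = 2)
  expect_identical(nrow(all1$retained@features), nrow(syn@features))

  # well-separated classes: unanimous votes, zero entropy, all retained
  flt <- uncertaintyFilter(X, y, syn, seed = 2)
  expect_identical(nrow(flt$retained@features), nrow(syn@features))
  expect_true(all(flt$retained@uncertainty == 0))

  # fixed seed reproduces the retained set exactly
  flt2 <- uncertaintyFilter(X, y, syn, seed = 2)
  expect_identical(flt$retained@features, flt2$retained@features)
})

test_that("outlier removal applies the mean + z*sd rule and deduplicates", {
  # one point at distance ~100 from a tight cluster of 20
  set.seed(41)
  X <- rbind(matrix(rnorm(40, sd = 0.5), ncol = 2), c(100, 100))
  colnames(X) <- c("f1", "f2")
  y <- rep("a", 21)
  kept <- removeOutliers(X, y, z = 3)
  expect_false(21L %in% kept)
  expect_true(all(1:20 %in% kept))

  # identical points: none removed by distance, collapsed to one by epsilon
  Xd <- matrix(1, nrow = 5, ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  expect_identical(removeOutliers(Xd, rep("a", 5)), 1L)

  # z = Inf, eps = 0 is the identity
  expect_identical(removeOutliers(X, y, z = Inf, eps = 0), 1:21)
})

test_that("K-means diagnostics recover well-separated blobs", {
  set.seed(51)
  centers <- cbind(c(0, 10, 0, 10, 5), c(0, 0, 10, 10, 5))
  X <- do.call(rbind, lapply(1:5, function(c)
    sweep(matrix(rnorm(20, sd = 0.3), ncol = 2), 2, centers[c, ], `+`)))
  colnames(X) <- c("f1", "f2")
  y <- rep(letters[1:5], each = 10)
  diag5 <- clusterDiagnostics(X, y, nClusters = 5, seed = 4)
  tab <- diag5$contingency
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_identical(dim(diag5$projection), c(50L, 2L))

  # single cluster and determinism
  expect_true(all(clusterDiagnostics(X, nClusters = 1, seed = 4)$clusters == 1))
  expect_identical(clusterDiagnostics(X, nClusters = 5, seed = 4)$clusters,
                   diag5$clusters)
})

test_that("executing a plan reaches targets and keeps block normalizations", {
  set.seed(61)
  seqs <- setNames(vapply(1:56, function(i)
    paste(sample(c("A", "C", "G", "U"), 60, TRUE), collapse = ""), character(1)),
    paste0("s", 1:56))
  labels <- setNames(c(rep("a", 30), rep("b", 20), rep("c", 6)), names(seqs))
  ds <- labelledSequenceSet(seqs, labels)
  fs <- assembleFeatures(ds, features = "3mer")
  X <- featureMatrix(fs)
  y <- unname(featureLabels(fs))

  plan <- defaultBalancingPlan(y, seed = 7)
  expect_identical(unname(plan@targetCounts[c("a", "b", "c")]), c(30L, 20L, 20L))

  bal <- suppressMessages(balanceDataset(X, y, plan, filter = FALSE))
  expect_identical(as.integer(table(bal$labels)[c("a", "b", "c")]), c(30L, 20L, 20L))
  expect_identical(sum(bal$synthetic), 14L)
  # convex combinations of normalized 64-blocks still sum to 1
  syn <- bal$features[bal$synthetic, , drop = FALSE]
  expect_equal(unname(rowSums(syn)), rep(1, nrow(syn)), tolerance = 1e-12)

  # with filtering, the bookkeeping matches the discard counts
  balF <- suppressMessages(balanceDataset(X, y, plan, filter = TRUE))
  rep <- balF$report$filter
  expect_identical(nrow(balF$features),
                   56L + rep$n - rep$discardedEntropy - rep$discardedVote)
})
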