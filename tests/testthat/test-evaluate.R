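test_that("confusion metrics match the one-vs-rest closed forms", {
  # TP=50 FN=10 FP=5 TN=100 for class "pos"
  yTrue <- c(rep("pos", 60), rep("neg", 105))
  yPred <- c(rep("pos", 50), rep("neg", 10), rep("pos", 5), rep("neg", 100))
  rep <- confusionMetrics(yTrue, yPred, c("neg", "pos"))
  pc <- rep@perClass["pos", ]
  expect_identical(c(pc$TP, pc$FN, pc$FP, pc$TN), c(50L, 10L, 5L, 100L))
  expect_equal(pc$Sn, 50 / 60, tolerance = 1e-9)
  expect_equal(pc$Sp, 100 / 105, tolerance = 1e-9)
  expect_equal(pc$MCC, 4950 / sqrt(55 * 60 * 105 * 110), tolerance = 1e-9)
  expect_equal(rep@acc, 150 / 165, tolerance = 1e-9)

  # perfect predictions
  perf <- confusionMetrics(yTrue, yTrue, c("neg", "pos"))
  expect_true(all(perf@perClass$Sn == 1) && all(perf@perClass$Sp == 1))
  expect_true(all(perf@perClass$MCC == 1))
  expect_identical(perf@acc, 1)

  # degenerate single-class prediction has MCC 0 by convention
  onec <- confusionMetrics(yTrue, rep("neg", 165), c("neg", "pos"))
  expect_equal(onec@perClass["pos", "MCC"], 0)

  expect_error(confusionMetrics("a", c("a", "b")), "differ")
  expect_error(confusionMetrics(character(0), character(0)), "empty")
})

test_that("micro accuracy equals mean per-sample correctness", {
  set.seed(111)
  for (i in 1:5) {
    yT <- sample(letters[1:4], 50, TRUE)
    yP <- sample(letters[1:4], 50, TRUE)
    expect_equal(confusionMetrics(yT, yP, letters[1:4])@acc, mean(yT == yP))
  }
})

test_that("ROC AUC matches the rank formulation and reference cases", {
  y <- rep(c("p", "n"), each = 10)
  sPerfect <- cbind(p = c(seq(0.9, 0.99, length.out = 10), seq(0.0, 0.4, length.out = 10)))
  expect_equal(unname(rocAuc(y, sPerfect, "p")$perClass), 1.0)
  expect_equal(unname(rocAuc(y, 1 - sPerfect, "p")$perClass), 0.0)

  # scores independent of labels: AUC near 1/2
  set.seed(121)
  y2 <- sample(c("p", "n"), 1000, TRUE)
  s2 <- cbind(p = runif(1000))
  expect_lt(abs(rocAuc(y2, s2, "p")$perClass[["p"]] - 0.5), 0.08)

  # Mann-Whitney equivalence on random instances with ties
  for (i in 1:10) {
    n <- sample(10:100, 1)
    yT <- sample(c("p", "n"), n, TRUE, prob = c(0.4, 0.6))
    if (length(unique(yT)) < 2) next
    sc <- cbind(p = round(runif(n), 1))  # coarse grid forces ties
    u <- unname(stats::wilcox.test(sc[yT == "p", "p"], sc[yT == "n", "p"],
                                   exact = FALSE)$statistic)
    expect_equal(unname(rocAuc(yT, sc, "p")$perClass),
                 u / (sum(yT == "p") * sum(yT == "n")), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with pROC and flags degenerate classes", {
  set.seed(131)
  y <- sample(c("p", "n"), 80, TRUE)
  sc <- cbind(p = runif(80))
  ours <- unname(rocAuc(y, sc, "p")$perClass)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y == "p", predictor = sc[, "p"],
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)

  # class without positives is NA and excluded from the macro average
  res <- rocAuc(rep("n", 10), cbind(n = runif(10), p = runif(10)), c("n", "p"))
  expect_true(is.na(res$perClass[["p"]]))
  expect_true(is.na(res$perClass[["n"]]))  # no negatives for "n" either
})

test_that("F-scores match the closed form, an oracle, and are scale invariant", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1, dimnames = list(NULL, "f"))
  y <- c("c1", "c1", "c2", "c2")
  expect_equal(unname(fscore(X, y)@scores), 2.0, tolerance = 1e-12)

  # constant feature scores exactly 0
  Xc <- cbind(f1 = rep(3, 6), f2 = rnorm(6))
  expect_equal(unname(fscore(Xc, rep(c("a", "b"), 3))@scores[["f1"]]), 0)

  set.seed(141)
  for (i in 1:20) {
    Xr <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
    yr <- sample(letters[1:3], 30, TRUE)
    if (any(table(yr) < 2)) next
    ours <- fscore(Xr, yr)@scores
    oracle <- fscoreOracle(Xr, yr)
    expect_lt(max(abs(ours - oracle) / pmax(abs(oracle), 1e-300)), 1e-10)
    # affine rescaling of features leaves F unchanged
    scaled <- fscore(sweep(sweep(Xr, 2, runif(20, 0.5, 3), `*`), 2, rnorm(20), `+`), yr)@scores
    expect_equal(unname(scaled), unname(ours), tolerance = 1e-9)
  }

  expect_error(fscore(X, c("c1", "c2", "c2", "c2")), "n_j >= 2")
})

test_that("ranking is a descending permutation with index tie-breaks", {
  X <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = rnorm(4, sd = 0.01))
  y <- c("x", "x", "y", "y")
  r <- fscore(X, y)
  expect_setequal(r@ranking, 1:3)
  # a and b tie exactly; lower index first
  expect_true(which(r@ranking == 1) < which(r@ranking == 2))
  expect_identical(topFeatures(r, 2), c("a", "b"))
})

test_that("stratified folds cover each sample once with balanced classes", {
  set.seed(151)
  y <- sample(c(rep("a", 55), rep("b", 33), rep("c", 12)))
  fold <- stratifiedFolds(y, folds = 5, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(length(fold), 100L)
  for (cls in c("a", "b", "c")) {
    perFold <- table(factor(fold[y == cls], levels = 1:5))
    expect_lte(max(perFold) - min(perFold), 1)
  }
  # class smaller than folds warns but folds are kept
  ySmall <- c(rep("a", 30), rep("b", 4))
  expect_warning(f2 <- stratifiedFolds(ySmall, 10, seed = 1), "fewer members")
  expect_identical(max(f2), 10L)
})

test_that("cross-validation tests every real sample once and never synthetics", {
  set.seed(161)
  centers <- matrix(c(0, 0, 5, 0, 0, 5), ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(c)
    sweep(matrix(rnorm(2 * c(24, 16, 8)[c], sd = 0.6), ncol = 2), 2, centers[c, ], `+`)))
  colnames(X) <- c("f1", "f2")
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  y <- rep(c("a", "b", "c"), times = c(24, 16, 8))
  cv <- suppressWarnings(suppressMessages(
    stratifiedKfoldCV(X, y, folds = 4, plan = "default", Tmax = 8, seed = 5)))
  # every sample predicted exactly once, predictions only for real rows
  expect_identical(length(cv$predictions), nrow(X))
  expect_false(any(cv$predictions == ""))
  expect_identical(sort(unique(cv$foldAssignment)), 1:4)
  expect_identical(sum(cv$report@confusion), nrow(X))
  expect_identical(rownames(cv$scores), rownames(X))
  # pooled report carries per-class AUC
  expect_false(any(is.na(cv$report@perClass$AUC)))
  # separable blobs should be essentially solved
  expect_gte(cv$report@acc, 0.9)
})

test_that("ablation rewards the block that carries the planted signal", {
  # class signal lives only in the RF2 block; the 3mer block is pure noise
  set.seed(171)
  n <- 90
  y <- rep(c("a", "b", "c"), each = n / 3)
  X3 <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("3mer:f", 1:6)))
  Xrf <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("RF2:g", 1:4)))
  Xrf[, 1] <- Xrf[, 1] + 2 * (y == "a")
  Xrf[, 2] <- Xrf[, 2] + 2 * (y == "b")
  X <- cbind(X3, Xrf)
  tab <- suppressWarnings(ablation(X, y,
    subsets = list(`3mer` = "3mer", `3mer+3rf` = c("3mer", "3rf")),
    folds = 3, plan = NULL, Tmax = 10, seed = 9))
  expect_identical(nrow(tab), 2L)
  expect_gt(tab$ACC[tab$subset == "3mer+3rf"], tab$ACC[tab$subset == "3mer"])

  expect_error(ablation(X, y, subsets = list(a = "3mer", a = "3mer")), "unique")
  expect_error(suppressWarnings(ablation(X, y, subsets = list(q = "nope"),
                                         folds = 3, plan = NULL, Tmax = 2)),
               "unknown|matches no")
})
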