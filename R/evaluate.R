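# Performance metrics, ROC/AUC, F-score feature ranking, stratified
# cross-validation with leakage-safe in-fold balancing, and feature ablation.

#' One-vs-rest confusion metrics
#'
#' Builds the k x k confusion matrix and, per class, the one-vs-rest counts
#' with Sn = TP/(TP+FN), Sp = TN/(TN+FP) and the Matthews correlation
#' coefficient (0 when its denominator vanishes, the usual convention).
#' Overall accuracy is trace/total.
#'
#' @param yTrue,yPred Equal-length label vectors, values within `classSet`.
#' @param classSet Ordered class set; defaults to the sorted union of labels.
#' @return A [MetricsReport-class] (AUC column `NA`; see [rocAuc()]).
#' @export
confusionMetrics <- function(yTrue, yPred, classSet = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("yTrue and yPred lengths differ")
  if (!length(yTrue)) stop("empty input")
  if (is.null(classSet)) classSet <- sort(unique(c(yTrue, yPred)))
  if (!all(c(yTrue, yPred) %in% classSet)) stop("labels outside classSet")
  cm <- table(factor(yTrue, classSet), factor(yPred, classSet))
  cm <- unclass(cm)
  total <- sum(cm)
  per <- do.call(rbind, lapply(seq_along(classSet), function(c) {
    TP <- cm[c, c]
    FN <- sum(cm[c, ]) - TP
    FP <- sum(cm[, c]) - TP
    TN <- total - TP - FN - FP
    den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
    data.frame(TP = TP, FN = FN, FP = FP, TN = TN,
               Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
               MCC = if (den > 0) (TP * TN - FP * FN) / den else 0,
               AUC = NA_real_)
  }))
  rownames(per) <- classSet
  new("MetricsReport", confusion = cm, perClass = per,
      acc = sum(diag(cm)) / total)
}

#' One-vs-rest ROC AUC
#'
#' Per class, the area under the ROC curve of that class's score column,
#' computed by the rank (Mann-Whitney) formulation so tied scores are handled
#' by midpoint. Classes without both a positive and a negative sample get
#' `NA` and are excluded from the macro average.
#'
#' @param yTrue Label vector.
#' @param scores Samples x classes score matrix (columns in `classSet`
#'   order).
#' @param classSet Ordered class set.
#' @return List with `perClass` (named AUC vector) and `macro`.
#' @export
rocAuc <- function(yTrue, scores, classSet = NULL) {
  yTrue <- as.character(yTrue)
  if (is.null(classSet)) classSet <- colnames(scores)
  if (is.null(classSet)) classSet <- sort(unique(yTrue))
  if (nrow(scores) != length(yTrue)) stop("score rows must align with samples")
  auc <- vapply(seq_along(classSet), function(c) {
    pos <- yTrue == classSet[c]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, c], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- classSet
  list(perClass = auc, macro = mean(auc, na.rm = TRUE))
}

#' ROC curve points for one class
#'
#' @param yTrue Label vector.
#' @param score Score column for the class of interest.
#' @param positiveClass The class treated as positive.
#' @return data.frame with `fpr`, `tpr` sorted for plotting; trapezoidal
#'   integration of these points equals the midpoint-tie AUC of [rocAuc()].
#' @export
rocCurve <- function(yTrue, score, positiveClass) {
  pos <- as.character(yTrue) == positiveClass
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(s) {
    c(fpr = sum(!pos & score >= s) / max(sum(!pos), 1),
      tpr = sum(pos & score >= s) / max(sum(pos), 1))
  }, numeric(2)))
  rbind(data.frame(fpr = 0, tpr = 0), as.data.frame(pts), data.frame(fpr = 1, tpr = 1))
}

#' F-score feature ranking
#'
#' For feature i with class means `m_ij`, grand mean `m_i` and class sizes
#' `n_j`:
#' `F_i = sum_j (m_ij - m_i)^2 / sum_j (1/(n_j - 1)) sum_k (x_kij - m_ij)^2`
#' — between-class over within-class scatter. A feature constant within all
#' classes gets a 1e-12 denominator guard (so an everywhere-constant feature
#' scores exactly 0). The measure is invariant to affine rescaling of a
#' feature. Ranks are descending, ties broken by feature index.
#'
#' @param X Feature matrix (samples x features).
#' @param y Labels; every class needs >= 2 members.
#' @return An [FScoreRanking-class].
#' @export
fscore <- function(X, y) {
  y <- as.character(y)
  cnt <- table(y)
  if (any(cnt < 2)) stop("every class needs n_j >= 2 for the within-class variance")
  classes <- names(cnt)
  grand <- colMeans(X)
  num <- rep(0, ncol(X)); den <- rep(0, ncol(X))
  for (cls in classes) {
    sub <- X[y == cls, , drop = FALSE]
    m <- colMeans(sub)
    num <- num + (m - grand)^2
    den <- den + colSums(sweep(sub, 2, m)^2) / (nrow(sub) - 1)
  }
  den[den == 0] <- den[den == 0] + 1e-12
  f <- num / den
  names(f) <- colnames(X)
  new("FScoreRanking", scores = f,
      ranking = as.integer(order(-f, seq_along(f))))
}

#' Top-ranked feature names
#'
#' @param ranking An [FScoreRanking-class].
#' @param n How many features.
#' @return Character vector of feature names, best first.
#' @export
topFeatures <- function(ranking, n) {
  stopifnot(is(ranking, "FScoreRanking"))
  names(ranking@scores)[ranking@ranking[seq_len(min(n, length(ranking@ranking)))]]
}

#' Stratified fold assignment
#'
#' Per class, samples are shuffled and spread over folds so per-fold class
#' counts differ by at most one. A class with fewer members than folds simply
#' leaves some folds without that class (warned); folds are only reduced when
#' there are fewer samples than folds.
#'
#' @param y Labels.
#' @param folds Number of folds (default 10).
#' @param seed Seed.
#' @return Integer fold id per sample.
#' @export
stratifiedFolds <- function(y, folds = 10L, seed = 1L) {
  y <- as.character(y)
  if (length(y) < folds) {
    warning("fewer samples than folds; reducing folds to ", length(y))
    folds <- length(y)
  }
  small <- names(which(table(y) < folds))
  if (length(small))
    warning("class(es) with fewer members than folds (",
            paste(small, collapse = ", "), "); some folds will lack them")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation with in-fold balancing
#'
#' For each fold, the training portion alone is (optionally) balanced by
#' oversampling ([balanceDataset()]); the model is trained on the augmented
#' training data and evaluated on the untouched held-out fold. Synthetic
#' samples therefore never leak into any test fold — every real sample is
#' tested exactly once, and only real samples are ever tested.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param folds Number of folds (default 10).
#' @param plan `NULL` for no balancing, `"default"` for
#'   [defaultBalancingPlan()], or a [BalancingPlan-class].
#' @param Tmax,depth,epsFloor Boosting configuration ([boostTrain()]).
#' @param seed Seed for fold assignment, balancing and training.
#' @param filter Apply [uncertaintyFilter()] inside each fold.
#' @return List with `report` (pooled [MetricsReport-class] including AUC),
#'   `auc` (the [rocAuc()] result), `perFold` reports, `foldAssignment`,
#'   `predictions` and `scores` (pooled, in input order).
#' @export
stratifiedKfoldCV <- function(X, y, folds = 10L, plan = "default", Tmax = 50L,
                              depth = 2L, epsFloor = 1e-10, seed = 1L,
                              filter = TRUE) {
  y <- as.character(y)
  classSet <- sort(unique(y))
  if (length(classSet) < 2L) stop("need at least two classes")
  fold <- stratifiedFolds(y, folds, seed)
  folds <- max(fold)
  pred <- character(length(y))
  scores <- matrix(NA_real_, length(y), length(classSet),
                   dimnames = list(rownames(X), classSet))
  perFold <- vector("list", folds)
  for (f in seq_len(folds)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    Xtr <- X[trainIdx, , drop = FALSE]
    ytr <- y[trainIdx]
    if (!is.null(plan)) {
      pl <- if (identical(plan, "default")) defaultBalancingPlan(ytr, seed = seed + f)
            else balancingPlan(plan@targetCounts, plan@smoteK, plan@dangerM,
                               plan@method, plan@seed + f)
      bal <- balanceDataset(Xtr, ytr, pl, filter = filter)
      Xtr <- bal$features; ytr <- bal$labels
      # leakage guard: the test fold is indexed from the original matrix only
      stopifnot(all(testIdx %in% seq_len(nrow(X))))
    }
    model <- boostTrain(Xtr, ytr, classSet = classSet, Tmax = Tmax,
                        depth = depth, epsFloor = epsFloor, seed = seed + f)
    Xte <- X[testIdx, , drop = FALSE]
    pred[testIdx] <- predict(model, Xte)
    sc <- predictScores(model, Xte)
    scores[testIdx, colnames(sc)] <- sc
    perFold[[f]] <- confusionMetrics(y[testIdx], pred[testIdx], classSet)
  }
  report <- confusionMetrics(y, pred, classSet)
  aucRes <- rocAuc(y, scores, classSet)
  report@perClass$AUC <- aucRes$perClass[rownames(report@perClass)]
  list(report = report, auc = aucRes, perFold = perFold,
       foldAssignment = fold, predictions = pred, scores = scores)
}

#' Feature-combination ablation under cross-validation
#'
#' Runs [stratifiedKfoldCV()] on named feature subsets (block tokens `3mer`,
#' `3rf`, `mfe`, or explicit manifest names) and tabulates macro-averaged
#' Sn/Sp/MCC with the overall accuracy per subset.
#'
#' @param X Feature matrix whose columns carry manifest names.
#' @param y Labels.
#' @param subsets Named list; each element is a character vector of block
#'   tokens and/or manifest names.
#' @param ... Passed to [stratifiedKfoldCV()].
#' @return data.frame, one row per subset: `subset`, `nFeatures`, `Sn`, `Sp`,
#'   `ACC`, `MCC` (Sn/Sp/ACC in %).
#' @export
ablation <- function(X, y, subsets, ...) {
  if (is.null(names(subsets)) || anyDuplicated(names(subsets)))
    stop("subsets must have unique names")
  manifest <- colnames(X)
  resolve <- function(tokens) {
    cols <- unlist(lapply(tokens, function(tk) {
      hit <- switch(tk,
        "3mer" = grep("^3mer:", manifest, value = TRUE),
        "3rf" = grep("^RF[123]:", manifest, value = TRUE),
        "mfe" = grep("^MFE$", manifest, value = TRUE),
        tk)
      if (!all(hit %in% manifest))
        stop("unknown feature name(s): ", paste(setdiff(hit, manifest), collapse = ", "))
      if (!length(hit)) stop("token '", tk, "' matches no feature")
      hit
    }))
    unique(cols)
  }
  rows <- lapply(names(subsets), function(nm) {
    cols <- resolve(subsets[[nm]])
    cv <- stratifiedKfoldCV(X[, cols, drop = FALSE], y, ...)
    per <- cv$report@perClass
    data.frame(subset = nm, nFeatures = length(cols),
               Sn = 100 * mean(per$Sn, na.rm = TRUE),
               Sp = 100 * mean(per$Sp, na.rm = TRUE),
               ACC = 100 * cv$report@acc,
               MCC = mean(per$MCC, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
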