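# Class balancing: Borderline-SMOTE and ADASYN oversampling, ensemble
# uncertainty filtering of synthetic points, outlier removal, and K-means /
# PCA diagnostics.
#
# All nearest-neighbour computations use Euclidean distance on the feature
# matrix after standardizing the MFE column (its kcal/mol scale would
# otherwise dominate the frequency blocks); interpolation itself happens on
# the raw features, so convex combinations preserve every per-block
# normalization of the parents exactly.

#' Construct a BalancingPlan
#'
#' @param targetCounts Named integer vector of per-class target sizes.
#' @param smoteK Minority neighbours available for interpolation (default 5).
#' @param dangerM Neighbourhood size for danger detection / difficulty ratios
#'   (default 5).
#' @param method Oversampler per class, `"borderline-smote"` or `"adasyn"`;
#'   a scalar is recycled to all classes.
#' @param seed Seed for all oversampling randomness.
#' @return A [BalancingPlan-class].
#' @export
balancingPlan <- function(targetCounts, smoteK = 5L, dangerM = 5L,
                          method = "borderline-smote", seed = 1L) {
  tc <- setNames(as.integer(round(targetCounts)), names(targetCounts))
  if (length(method) == 1L) method <- setNames(rep(method, length(tc)), names(tc))
  new("BalancingPlan", targetCounts = tc, smoteK = as.integer(smoteK),
      dangerM = as.integer(dangerM), method = method, seed = as.integer(seed))
}

#' Default plan: raise minorities toward the second-largest class
#'
#' Every class below the second-largest class count is raised to it, except
#' that very small classes are capped at `cap` times their original size (so
#' a handful of real points is never asked to seed an arbitrarily large
#' synthetic cloud).
#'
#' @param y Class labels of the training data.
#' @param cap Maximum oversampling factor for any class (default 20).
#' @inheritParams balancingPlan
#' @return A [BalancingPlan-class].
#' @export
defaultBalancingPlan <- function(y, cap = 20L, smoteK = 5L, dangerM = 5L,
                                 method = "borderline-smote", seed = 1L) {
  cnt <- table(y)
  if (length(cnt) < 2L) stop("need at least two classes")
  second <- sort(as.integer(cnt), decreasing = TRUE)[2]
  tc <- pmax(as.integer(cnt), pmin(second, cap * as.integer(cnt)))
  balancingPlan(setNames(tc, names(cnt)), smoteK, dangerM, method, seed)
}

# dangerM nearest neighbours (excluding self) of each minority point in the
# full standardized set; returns the count of majority neighbours per point.
.majorityNeighbourCounts <- function(D, minIdx, y, targetClass, m) {
  vapply(minIdx, function(i) {
    nb <- order(D[i, -i])  # positions in the vector without i
    others <- seq_len(ncol(D))[-i]
    nb <- others[nb[seq_len(min(m, length(others)))]]
    sum(y[nb] != targetClass)
  }, integer(1))
}

.interpolate <- function(X, a, b, u) X[a, ] + u * (X[b, ] - X[a, ])

#' Borderline (DANGER) members of a minority class
#'
#' Minority samples whose `m`-neighbourhood in the full dataset (Euclidean,
#' MFE-standardized) contains at least `m/2` but fewer than `m` majority
#' samples — near the class boundary but not engulfed by the majority.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param targetClass The minority class.
#' @param m Neighbourhood size (default 5).
#' @return Integer row indices of the DANGER samples.
#' @export
dangerSet <- function(X, y, targetClass, m = 5L) {
  minIdx <- which(y == targetClass)
  D <- as.matrix(dist(.distanceReady(X)))
  maj <- .majorityNeighbourCounts(D, minIdx, y, targetClass, m)
  minIdx[maj >= m / 2 & maj < m]
}

.newSyntheticSet <- function(feats, pa, pb, u, cls) {
  feats <- if (length(pa)) do.call(rbind, feats) else
    matrix(numeric(0), 0, 0)
  new("SyntheticSampleSet", features = feats,
      parentA = as.integer(pa), parentB = as.integer(pb),
      u = as.numeric(u), classLabel = rep(cls, length(pa)),
      uncertainty = rep(NA_real_, length(pa)))
}

# smoteK nearest minority neighbours of minority point i (indices into X rows)
.minorityNeighbours <- function(D, minIdx, i, k) {
  others <- setdiff(minIdx, i)
  others[order(D[i, others])][seq_len(min(k, length(others)))]
}

#' Borderline-SMOTE oversampling of one class
#'
#' Borderline-SMOTE1: minority points whose `dangerM`-neighbourhood in the
#' full dataset is at least half majority (but not entirely majority — those
#' are treated as noise) form the DANGER set; synthetic points are
#' interpolated from DANGER points (round-robin over a seeded shuffle) toward
#' one of their `smoteK` nearest minority neighbours, with a fresh
#' `u ~ Uniform(0, 1)` per sample. If the DANGER set is empty the sampler
#' falls back to classic SMOTE over all minority points (reported via
#' `attr(x, "fallback")` and a message).
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Class labels, one per row.
#' @param targetClass Class to oversample (must have >= 2 members).
#' @param nNew Number of synthetic samples to create.
#' @param plan A [BalancingPlan-class] supplying `smoteK`, `dangerM`, `seed`.
#' @return A [SyntheticSampleSet-class] with exactly `nNew` samples.
#' @export
borderlineSmote <- function(X, y, targetClass, nNew,
                            plan = balancingPlan(setNames(integer(0), character(0)))) {
  minIdx <- which(y == targetClass)
  if (length(minIdx) < 2L) stop("minority class '", targetClass, "' has < 2 members")
  if (nNew <= 0L) return(.newSyntheticSet(list(), integer(0), integer(0), numeric(0), targetClass))
  D <- as.matrix(dist(.distanceReady(X)))
  m <- plan@dangerM
  danger <- dangerSet(X, y, targetClass, m)
  fallback <- length(danger) == 0L
  if (fallback) {
    message("borderlineSmote: DANGER set empty for '", targetClass,
            "'; falling back to classic SMOTE")
    danger <- minIdx
  }
  set.seed(plan@seed)
  danger <- danger[sample.int(length(danger))]
  feats <- vector("list", nNew)
  pa <- pb <- integer(nNew)
  uu <- numeric(nNew)
  for (s in seq_len(nNew)) {
    i <- danger[((s - 1L) %% length(danger)) + 1L]
    nbs <- .minorityNeighbours(D, minIdx, i, plan@smoteK)
    z <- nbs[sample.int(length(nbs), 1L)]
    u <- runif(1)
    feats[[s]] <- .interpolate(X, i, z, u)
    pa[s] <- i; pb[s] <- z; uu[s] <- u
  }
  out <- .newSyntheticSet(feats, pa, pb, uu, targetClass)
  attr(out, "fallback") <- fallback
  out
}

#' ADASYN oversampling of one class
#'
#' Adaptive allocation: each minority point i gets difficulty
#' `r_i = (majority neighbours among its dangerM nearest) / dangerM`; the
#' deficit is allocated as `g_i = round(nNew * r_i / sum(r))`, with the
#' rounding residue assigned to (or removed from) the most (least) difficult
#' points. If all `r_i = 0` the allocation falls back to uniform (reported).
#' Each point then synthesizes its `g_i` samples toward random minority
#' neighbours exactly as in SMOTE.
#'
#' @inheritParams borderlineSmote
#' @return A [SyntheticSampleSet-class] with exactly `nNew` samples;
#'   `attr(x, "allocation")` records the per-point allocation.
#' @export
adasyn <- function(X, y, targetClass, nNew,
                   plan = balancingPlan(setNames(integer(0), character(0)))) {
  minIdx <- which(y == targetClass)
  if (length(minIdx) < 2L) stop("minority class '", targetClass, "' has < 2 members")
  if (nNew <= 0L) return(.newSyntheticSet(list(), integer(0), integer(0), numeric(0), targetClass))
  D <- as.matrix(dist(.distanceReady(X)))
  m <- plan@dangerM
  r <- .majorityNeighbourCounts(D, minIdx, y, targetClass, m) / m
  if (sum(r) == 0) {
    message("adasyn: all difficulty ratios are 0 for '", targetClass,
            "'; uniform allocation")
    g <- rep(nNew %/% length(minIdx), length(minIdx))
    extra <- nNew - sum(g)
    if (extra > 0) g[seq_len(extra)] <- g[seq_len(extra)] + 1L
  } else {
    g <- round(nNew * r / sum(r))
    resid <- nNew - sum(g)
    ord <- order(-r, seq_along(r))  # most difficult first, ties by index
    while (resid > 0) {
      for (i in ord) {
        if (resid == 0) break
        g[i] <- g[i] + 1L; resid <- resid - 1L
      }
    }
    while (resid < 0) {
      for (i in rev(ord)) {
        if (resid == 0) break
        if (g[i] > 0) { g[i] <- g[i] - 1L; resid <- resid + 1L }
      }
    }
  }
  set.seed(plan@seed)
  feats <- list(); pa <- pb <- integer(0); uu <- numeric(0)
  for (q in seq_along(minIdx)) {
    i <- minIdx[q]
    if (g[q] == 0) next
    nbs <- .minorityNeighbours(D, minIdx, i, plan@smoteK)
    for (s in seq_len(g[q])) {
      z <- nbs[sample.int(length(nbs), 1L)]
      u <- runif(1)
      feats <- c(feats, list(.interpolate(X, i, z, u)))
      pa <- c(pa, i); pb <- c(pb, z); uu <- c(uu, u)
    }
  }
  out <- .newSyntheticSet(feats, pa, pb, uu, targetClass)
  attr(out, "allocation") <- setNames(g, minIdx)
  out
}

#' Filter synthetic samples by ensemble uncertainty
#'
#' Trains `ensembleSize` shallow weighted-Gini trees on seeded bootstrap
#' resamples of the real data and scores every synthetic sample by its
#' predictive-vote entropy `H = -sum_c p_c ln p_c` (nats). Samples with
#' `H > tau`, or whose ensemble majority vote disagrees with their assigned
#' class (when `majorityCheck = TRUE`), are discarded. This is the package's
#' interpretation of confidence-based filtering of oversampled points; the
#' defaults (25 trees, `tau = 0.75 ln k`) are configurable.
#'
#' @param X Real (non-synthetic) feature matrix.
#' @param y Real labels.
#' @param synthetic A [SyntheticSampleSet-class].
#' @param tau Entropy threshold in nats; default `0.75 * log(k)`.
#' @param ensembleSize Number of bootstrap trees (default 25).
#' @param depth Tree depth (default 2).
#' @param seed Seed for the bootstrap resamples.
#' @param majorityCheck Also require the majority vote to match the assigned
#'   class (default `TRUE`).
#' @return List with `retained` (a [SyntheticSampleSet-class] whose
#'   `uncertainty` slot holds the vote entropies), `kept` (logical over the
#'   input samples) and `report` (discard counts).
#' @export
uncertaintyFilter <- function(X, y, synthetic, tau = NULL, ensembleSize = 25L,
                              depth = 2L, seed = 1L, majorityCheck = TRUE) {
  classes <- sort(unique(as.character(y)))
  k <- length(classes)
  if (is.null(tau)) tau <- 0.75 * log(k)
  if (tau <= 0) stop("tau must be > 0")
  nSyn <- nrow(synthetic@features)
  if (nSyn == 0L)
    return(list(retained = synthetic, kept = logical(0),
                report = list(n = 0L, discardedEntropy = 0L, discardedVote = 0L)))
  yc <- match(y, classes) - 1L
  n <- nrow(X)
  set.seed(seed)
  votes <- matrix(0L, nrow = nSyn, ncol = k)
  for (b in seq_len(ensembleSize)) {
    boot <- sample.int(n, n, replace = TRUE)
    tree <- fitTreeCpp(X[boot, , drop = FALSE], yc[boot], rep(1 / n, n), k, depth)
    pred <- predictTreeCpp(tree, synthetic@features) + 1L
    votes[cbind(seq_len(nSyn), pred)] <- votes[cbind(seq_len(nSyn), pred)] + 1L
  }
  p <- votes / ensembleSize
  H <- -rowSums(ifelse(p > 0, p * log(p), 0))
  majClass <- classes[max.col(votes, ties.method = "first")]
  badEntropy <- H > tau
  badVote <- majorityCheck & (majClass != synthetic@classLabel)
  kept <- !(badEntropy | badVote)
  retained <- new("SyntheticSampleSet",
                  features = synthetic@features[kept, , drop = FALSE],
                  parentA = synthetic@parentA[kept],
                  parentB = synthetic@parentB[kept],
                  u = synthetic@u[kept],
                  classLabel = synthetic@classLabel[kept],
                  uncertainty = H[kept])
  list(retained = retained, kept = kept,
       report = list(n = nSyn,
                     discardedEntropy = sum(badEntropy),
                     discardedVote = sum(badVote & !badEntropy)))
}

#' Remove per-class outliers and near-duplicates
#'
#' Per class, samples farther than `mean(d) + z * sd(d)` from the class
#' centroid (Euclidean, MFE-standardized) are removed; afterwards any sample
#' whose feature vector lies strictly within `eps` of an earlier retained
#' sample is removed as a near-duplicate (a stand-in for de-correlating the
#' balanced dataset).
#'
#' @param X Feature matrix.
#' @param y Labels (every class needs >= 2 members).
#' @param z Distance-rule multiplier (default 3; `Inf` disables).
#' @param eps Near-duplicate radius (default 1e-9; `0` disables).
#' @return Integer vector of retained row indices, in original order.
#' @export
removeOutliers <- function(X, y, z = 3.0, eps = 1e-9) {
  cnt <- table(y)
  if (any(cnt < 2)) stop("every class needs >= 2 members")
  Xd <- .distanceReady(X)
  keep <- rep(TRUE, nrow(X))
  for (cls in names(cnt)) {
    idx <- which(y == cls)
    ctr <- colMeans(Xd[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(Xd[idx, , drop = FALSE], 2, ctr)^2))
    lim <- mean(d) + z * stats::sd(d)
    if (!is.na(lim)) keep[idx[d > lim]] <- FALSE
  }
  retained <- which(keep)
  if (eps > 0 && length(retained) > 1L) {
    D <- as.matrix(dist(Xd[retained, , drop = FALSE]))
    dupe <- rep(FALSE, length(retained))
    for (q in 2:length(retained)) {
      if (any(D[q, seq_len(q - 1L)][!dupe[seq_len(q - 1L)]] < eps)) dupe[q] <- TRUE
    }
    retained <- retained[!dupe]
  }
  retained
}

#' K-means / PCA diagnostics of a feature matrix
#'
#' K-means with k-means++ seeding and 10 restarts, plus the first two
#' principal components, for eyeballing whether balanced classes occupy
#' separate regions of feature space.
#'
#' @param X Feature matrix.
#' @param y Optional labels for the cluster-vs-class contingency table.
#' @param nClusters Number of clusters (default 5).
#' @param seed Seed.
#' @return List with `clusters`, `projection` (n x 2), `contingency` (or
#'   `NULL`), and `totWithinss`.
#' @export
clusterDiagnostics <- function(X, y = NULL, nClusters = 5L, seed = 1L) {
  if (nClusters > nrow(X)) stop("nClusters exceeds the number of samples")
  Xd <- .distanceReady(X)
  set.seed(seed)
  best <- NULL
  for (r in 1:10) {
    centers <- .kmeansppInit(Xd, nClusters)
    fit <- suppressWarnings(stats::kmeans(Xd, centers = centers, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  pcs <- if (nrow(Xd) >= 2) {
    pr <- stats::prcomp(Xd, center = TRUE, scale. = FALSE)
    cbind(PC1 = pr$x[, 1],
          PC2 = if (ncol(pr$x) >= 2) pr$x[, 2] else 0)
  } else matrix(0, nrow(Xd), 2, dimnames = list(NULL, c("PC1", "PC2")))
  contingency <- if (!is.null(y)) table(cluster = best$cluster, class = y) else NULL
  list(clusters = best$cluster, projection = pcs,
       contingency = contingency, totWithinss = best$tot.withinss)
}

.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(centers, 1, function(ct) rowSums(sweep(X, 2, ct)^2))
    mind <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    if (sum(mind) == 0) pick <- sample.int(n, 1L)
    else pick <- sample.int(n, 1L, prob = mind)
    centers <- rbind(centers, X[pick, , drop = FALSE])
  }
  unname(centers)
}

#' Execute a balancing plan
#'
#' Oversamples every class whose target exceeds its current count (method per
#' class from the plan), then filters the pooled synthetic points with
#' [uncertaintyFilter()]. Real samples are never modified or removed.
#'
#' @param X Feature matrix of real samples.
#' @param y Labels.
#' @param plan A [BalancingPlan-class]; `NULL` uses [defaultBalancingPlan()].
#' @param filter Apply the uncertainty filter (default `TRUE`).
#' @param ... Passed to [uncertaintyFilter()].
#' @return List with `features` (real rows first, then retained synthetic),
#'   `labels`, `synthetic` (logical flag per row), `report` (per-class
#'   deficits and filter discard counts) and `samples` (the retained
#'   [SyntheticSampleSet-class]).
#' @export
balanceDataset <- function(X, y, plan = NULL, filter = TRUE, ...) {
  y <- as.character(y)
  if (is.null(plan)) plan <- defaultBalancingPlan(y)
  synths <- list()
  deficits <- list()
  for (cls in names(plan@targetCounts)) {
    cur <- sum(y == cls)
    deficit <- plan@targetCounts[[cls]] - cur
    deficits[[cls]] <- max(deficit, 0L)
    if (deficit <= 0L || cur == 0L) next
    sub <- balancingPlan(plan@targetCounts, plan@smoteK, plan@dangerM,
                         plan@method, plan@seed + match(cls, names(plan@targetCounts)))
    synths[[cls]] <- switch(plan@method[[cls]],
      "borderline-smote" = borderlineSmote(X, y, cls, deficit, sub),
      "adasyn" = adasyn(X, y, cls, deficit, sub))
  }
  pooled <- .rbindSynthetic(synths, ncol(X), colnames(X))
  if (filter && nrow(pooled@features) > 0) {
    fl <- uncertaintyFilter(X, y, pooled, seed = plan@seed, ...)
    pooled <- fl$retained
    filterReport <- fl$report
  } else {
    filterReport <- list(n = nrow(pooled@features), discardedEntropy = 0L,
                         discardedVote = 0L)
  }
  feats <- rbind(X, pooled@features)
  rownames(feats) <- NULL
  list(features = feats,
       labels = c(y, pooled@classLabel),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(pooled@features))),
       report = list(deficits = unlist(deficits), filter = filterReport),
       samples = pooled)
}

.rbindSynthetic <- function(synths, p, cn) {
  synths <- Filter(function(s) nrow(s@features) > 0, synths)
  if (!length(synths))
    return(new("SyntheticSampleSet",
               features = matrix(numeric(0), 0, p, dimnames = list(NULL, cn)),
               parentA = integer(0), parentB = integer(0), u = numeric(0),
               classLabel = character(0), uncertainty = numeric(0)))
  new("SyntheticSampleSet",
      features = do.call(rbind, lapply(synths, function(s) s@features)),
      parentA = unlist(lapply(synths, function(s) s@parentA), use.names = FALSE),
      parentB = unlist(lapply(synths, function(s) s@parentB), use.names = FALSE),
      u = unlist(lapply(synths, function(s) s@u), use.names = FALSE),
      classLabel = unlist(lapply(synths, function(s) s@classLabel), use.names = FALSE),
      uncertainty = unlist(lapply(synths, function(s) s@uncertainty), use.names = FALSE))
}
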