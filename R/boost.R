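# Multiclass AdaBoost with the SAMME-style round coefficient
# alpha_t = 1/2 log((1 - eps_t)/eps_t) + log(k - 1)
# and exponential reweighting of samples each round.

#' Round coefficient of the multiclass booster
#'
#' `alpha = 1/2 * log((1 - epsilon)/epsilon) + log(k - 1)` (natural log).
#' For k = 2 this reduces to the classic binary AdaBoost coefficient.
#' Positivity holds iff `epsilon < (k-1)^2 / ((k-1)^2 + 1)`; note this is a
#' weaker requirement than "better than random" `1 - 1/k` for k > 2 — the
#' half-weighted error term moves the boundary (about 0.941 for k = 5, not
#' 0.8).
#'
#' @param epsilon Weighted error in (0, 1).
#' @param k Number of classes (>= 2).
#' @return The coefficient (may be negative; callers stop boosting at <= 0).
#' @export
alphaCoefficient <- function(epsilon, k) {
  if (k < 2) stop("k must be >= 2")
  if (any(epsilon <= 0) || any(epsilon >= 1)) stop("epsilon must lie strictly in (0, 1)")
  0.5 * log((1 - epsilon) / epsilon) + log(k - 1)
}

#' Train the boosted multiclass model
#'
#' Initializes uniform sample weights; each round fits a depth-limited
#' weighted-Gini decision tree, computes the weighted error `eps_t` (clamped
#' to `[epsFloor, 1 - epsFloor]` so a perfectly fit round keeps a finite
#' coefficient), converts it to `alpha_t`, and reweights: correct samples are
#' multiplied by `exp(-alpha_t)`, wrong samples by `exp(+alpha_t)`, then the
#' weights are renormalized to sum to 1. Training stops early when
#' `alpha_t <= 0` (the base learner hit the multiclass positivity boundary);
#' a non-positive first round is an error. A round whose unclamped error is
#' already at the floor (a perfect fit) is kept and ends training, since any
#' further round would refit the same tree.
#'
#' Training is fully deterministic given the data order: the tree fitter
#' breaks split ties by lowest feature index, then lowest threshold.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Class labels.
#' @param classSet Ordered class set; defaults to `sort(unique(y))`.
#' @param Tmax Maximum number of rounds (default 50).
#' @param depth Base-tree depth (default 2).
#' @param epsFloor Clamp for the weighted error (default 1e-10).
#' @param seed Recorded in the model; training itself uses no randomness.
#' @return A [BoostModel-class]. `model@config` keeps the per-round weighted
#'   errors (`epsilons`) and the weight sums after each renormalization
#'   (`weightSums`).
#' @export
boostTrain <- function(X, y, classSet = NULL, Tmax = 50L, depth = 2L,
                       epsFloor = 1e-10, seed = 1L) {
  y <- as.character(y)
  if (is.null(classSet)) classSet <- sort(unique(y))
  if (!all(y %in% classSet)) stop("labels outside classSet")
  k <- length(classSet)
  if (k < 2L) stop("need at least two classes in the training data")
  if (Tmax < 1L) stop("Tmax must be >= 1")
  yc <- match(y, classSet) - 1L
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  epsilons <- numeric(0); weightSums <- numeric(0)
  for (t in seq_len(Tmax)) {
    tree <- fitTreeCpp(X, yc, w, k, depth)
    pred <- predictTreeCpp(tree, X)
    miss <- pred != yc
    rawEps <- sum(w[miss])
    eps <- min(max(rawEps, epsFloor), 1 - epsFloor)
    alpha <- alphaCoefficient(eps, k)
    if (alpha <= 0) {
      if (t == 1L)
        stop("first-round base learner is no better than the multiclass bound ",
             "(alpha <= 0); cannot boost")
      break
    }
    trees[[t]] <- tree
    alphas[t] <- alpha
    epsilons[t] <- eps
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    weightSums[t] <- sum(w)
    # a perfectly fit round ends boosting: further rounds would repeat it
    if (rawEps <= epsFloor) break
  }
  new("BoostModel", trees = trees, alphas = alphas, classSet = classSet,
      config = list(depth = as.integer(depth), Tmax = as.integer(Tmax),
                    epsFloor = epsFloor, seed = as.integer(seed),
                    nFeatures = ncol(X), epsilons = epsilons,
                    weightSums = weightSums))
}

.checkFeatureDim <- function(object, X) {
  if (!is.null(object@config$nFeatures) && ncol(X) != object@config$nFeatures)
    stop("feature dimension mismatch: model expects ", object@config$nFeatures,
         " features, got ", ncol(X))
}

.voteMatrix <- function(object, X) {
  k <- length(object@classSet)
  votes <- matrix(0, nrow(X), k, dimnames = list(rownames(X), object@classSet))
  for (t in seq_along(object@trees)) {
    pred <- predictTreeCpp(object@trees[[t]], X) + 1L
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + object@alphas[t]
  }
  votes
}

#' Predict classes with a boosted model
#'
#' Weighted vote: `argmax_c sum_t alpha_t [h_t(x) = c]`, ties resolved to the
#' first class in `classSet` order.
#'
#' @param object A [BoostModel-class].
#' @param newdata Feature matrix with the same columns the model was trained
#'   on.
#' @return Character vector of predicted classes.
#' @export
setMethod("predict", "BoostModel", function(object, newdata, ...) {
  if (!length(object@trees)) stop("empty model")
  .checkFeatureDim(object, newdata)
  votes <- .voteMatrix(object, newdata)
  object@classSet[max.col(votes, ties.method = "first")]
})

#' Per-class prediction scores
#'
#' Normalized vote mass `s_c(x) = sum_t alpha_t [h_t(x) = c] / sum_t alpha_t`;
#' every row sums to 1, and the row argmax equals [predict()]'s label.
#'
#' @param object A [BoostModel-class].
#' @param newdata Feature matrix.
#' @return Numeric matrix, samples x classes.
#' @export
predictScores <- function(object, newdata) {
  stopifnot(is(object, "BoostModel"))
  if (!length(object@trees)) stop("empty model")
  .checkFeatureDim(object, newdata)
  .voteMatrix(object, newdata) / sum(object@alphas)
}

#' Serialize a boosted model to JSON
#'
#' Trees are stored as flat split records (feature index, threshold, child
#' pointers, leaf class), so the file is self-describing and reloads to a
#' model with identical predictions.
#'
#' @param model A [BoostModel-class].
#' @param path Output path.
#' @export
writeBoostModel <- function(model, path) {
  stopifnot(is(model, "BoostModel"))
  obj <- list(classSet = model@classSet, alphas = model@alphas,
              config = model@config, trees = model@trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Reload a boosted model from JSON
#'
#' @param path Path written by [writeBoostModel()].
#' @return A [BoostModel-class].
#' @export
readBoostModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(if (is.data.frame(obj$trees)) nrow(obj$trees) else length(obj$trees)),
                  function(t) {
    tr <- if (is.data.frame(obj$trees)) lapply(obj$trees, function(col) col[[t]]) else obj$trees[[t]]
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         pred = as.integer(tr$pred))
  })
  cfg <- obj$config
  cfg$epsilons <- as.numeric(cfg$epsilons)
  cfg$weightSums <- as.numeric(cfg$weightSums)
  new("BoostModel", trees = trees, alphas = as.numeric(obj$alphas),
      classSet = as.character(obj$classSet), config = cfg)
}
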