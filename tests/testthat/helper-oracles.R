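# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: enumeration instead of dynamic programming, direct
# loops instead of vectorized algebra.

# --- exhaustive folding oracle -------------------------------------------

# all nested pairings of positions i..j (1-based) as lists of pair matrices
enumeratePairings <- function(bases, minHairpin = 3L, allowGU = TRUE) {
  pairable <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "CG", "GC") || (allowGU && p %in% c("GU", "UG"))
  }
  n <- length(bases)
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)  # i unpaired
    mFirst <- i + minHairpin + 1L
    for (m in (if (mFirst <= j) mFirst:j else integer(0))) {
      if (!pairable(bases[i], bases[m])) next
      for (inner in rec(i + 1L, m - 1L)) for (outer in rec(m + 1L, j)) {
        out <- c(out, list(rbind(c(i, m), inner, outer)))
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# independent loop-decomposition scorer over a pair list
scorePairingOracle <- function(bases, pairs, model) {
  if (nrow(pairs) == 0L) return(0)
  stk <- model@stacking
  ptype <- function(i, j) match(paste0(bases[i], bases[j]), rownames(stk))
  partner <- integer(length(bases))
  for (r in seq_len(nrow(pairs))) {
    partner[pairs[r, 1]] <- pairs[r, 2]
    partner[pairs[r, 2]] <- pairs[r, 1]
  }
  kidsOf <- function(i, j) {
    out <- list()
    p <- i + 1L
    while (p < j) {
      if (partner[p] > p) { out <- c(out, list(c(p, partner[p]))); p <- partner[p] + 1L }
      else p <- p + 1L
    }
    out
  }
  scoreOne <- function(i, j) {
    kids <- kidsOf(i, j)
    if (length(kids) == 0L) return(model@hairpinPenalty)
    if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      g1 <- k - i - 1L; g2 <- j - l - 1L
      inner <- scoreOne(k, l)
      if (g1 + g2 == 0L) return(stk[ptype(i, j), ptype(k, l)] + inner)
      if (g1 == 0L || g2 == 0L)
        return(model@bulgeBase + model@bulgeSlope * (g1 + g2) + inner)
      return(model@interiorBase + model@interiorSlope * (g1 + g2) + inner)
    }
    model@multiBase + model@multiBranch * length(kids) +
      sum(vapply(kids, function(kl) scoreOne(kl[1], kl[2]), numeric(1)))
  }
  sum(vapply(kidsOf(0L, length(bases) + 1L),
             function(kl) scoreOne(kl[1], kl[2]), numeric(1)))
}

bruteForceMfe <- function(seq, model) {
  bases <- strsplit(seq, "")[[1]]
  cands <- enumeratePairings(bases, model@minHairpin, model@allowGU)
  min(vapply(cands, function(p) scorePairingOracle(bases, p, model), numeric(1)))
}

# --- classic binary AdaBoost oracle --------------------------------------

# uses the same base learner (so tree choices are shared) but reimplements
# the boosting loop with the classic binary coefficient
classicAdaboostTrace <- function(X, y, classSet, Tmax, depth, epsFloor = 1e-10) {
  yc <- match(y, classSet) - 1L
  n <- nrow(X)
  w <- rep(1 / n, n)
  alphas <- numeric(0)
  trees <- list()
  for (t in seq_len(Tmax)) {
    tree <- lncBoost:::fitTreeCpp(X, yc, w, 2L, as.integer(depth))
    pred <- lncBoost:::predictTreeCpp(tree, X)
    miss <- pred != yc
    rawEps <- sum(w[miss])
    eps <- min(max(rawEps, epsFloor), 1 - epsFloor)
    alpha <- 0.5 * log((1 - eps) / eps)
    if (alpha <= 0) break
    alphas[t] <- alpha
    trees[[t]] <- tree
    if (rawEps <= epsFloor) break
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
  }
  pred <- function(Xn) {
    votes <- matrix(0, nrow(Xn), 2)
    for (t in seq_along(trees)) {
      p <- lncBoost:::predictTreeCpp(trees[[t]], Xn) + 1L
      votes[cbind(seq_len(nrow(Xn)), p)] <- votes[cbind(seq_len(nrow(Xn)), p)] + alphas[t]
    }
    classSet[max.col(votes, ties.method = "first")]
  }
  list(alphas = alphas, predict = pred)
}

# --- naive F-score oracle -------------------------------------------------

fscoreOracle <- function(X, y) {
  classes <- sort(unique(y))
  vapply(seq_len(ncol(X)), function(i) {
    xi <- X[, i]
    num <- 0; den <- 0
    for (cls in classes) {
      v <- xi[y == cls]
      num <- num + (mean(v) - mean(xi))^2
      den <- den + sum((v - mean(v))^2) / (length(v) - 1)
    }
    if (den == 0) den <- den + 1e-12
    num / den
  }, numeric(1))
}

# --- brute-force k-NN helpers --------------------------------------------

bruteKnn <- function(X, i, k, candidates = setdiff(seq_len(nrow(X)), i)) {
  d <- vapply(candidates, function(j) sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1))
  candidates[order(d)][seq_len(min(k, length(candidates)))]
}

bruteDangerSet <- function(X, y, targetClass, m) {
  minIdx <- which(y == targetClass)
  maj <- vapply(minIdx, function(i) {
    nb <- bruteKnn(X, i, m)
    sum(y[nb] != targetClass)
  }, integer(1))
  minIdx[maj >= m / 2 & maj < m]
}
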