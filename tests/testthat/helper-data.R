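# Shared toy fixtures, built in code.

# two borderline minority points amid three close majority points and one far
# majority outlier — danger membership is computable by hand
borderToy <- function() {
  X <- rbind(c(0, 0), c(1, 0),
             c(0.4, 0.1), c(0.5, -0.1), c(0.6, 0.1), c(5, 5))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = c("min", "min", "maj", "maj", "maj", "maj"))
}

# 1-D geometry engineered so the minority difficulty ratios under m = 5 are
# exactly (1, 0.2, 0, 0, 0, 0, 0, 0): one minority point engulfed by majority,
# one near the boundary, six in a pure minority cluster
adasynToy <- function() {
  minX <- c(10, 1.0, 0, 0.01, 0.02, 0.03, 0.04, 0.05)
  majX <- c(10.1, 10.2, 10.3, 10.4, 10.5, 1.05, seq(100, 109))
  X <- matrix(c(minX, majX), ncol = 1, dimnames = list(NULL, "f1"))
  list(X = X, y = c(rep("min", length(minX)), rep("maj", length(majX))))
}

# two gaussian classes in 2-D
gaussToy2 <- function(n, seed, sep = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = sep), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("a", "b"), each = n))
}
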