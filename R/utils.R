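# Shared constants and small helpers.

RNA_BASES <- c("A", "C", "G", "U")

# 64 triplets in lexicographic A < C < G < U order; this fixed order defines
# the layout of every 64-block in the feature vector.
tripletAlphabet <- function() {
  g <- expand.grid(b3 = RNA_BASES, b2 = RNA_BASES, b1 = RNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

TRIPLETS <- tripletAlphabet()

# NULL if the dot-bracket string is well formed, otherwise a message.
.dotBracketProblem <- function(s) {
  if (grepl("[^().]", s)) return("structure contains characters outside {(, ), .}")
  v <- strsplit(s, "")[[1]]
  depth <- cumsum((v == "(") - (v == ")"))
  if (length(depth) && min(depth) < 0) return("unbalanced brackets: ')' before its '('")
  if (length(depth) && depth[length(depth)] != 0) return("unbalanced brackets: unclosed '('")
  NULL
}

.assertDotBracket <- function(s, what = "structure") {
  msg <- .dotBracketProblem(s)
  if (!is.null(msg)) stop(what, ": ", msg, call. = FALSE)
  invisible(s)
}

# Uppercase, DNA -> RNA.
.normalizeResidues <- function(x) chartr("T", "U", toupper(x))

.asRnaString <- function(seq) {
  if (is(seq, "RNAString")) return(seq)
  if (is(seq, "RNAStringSet") && length(seq) == 1L) return(seq[[1]])
  if (is.character(seq) && length(seq) == 1L) {
    s <- .normalizeResidues(seq)
    if (grepl("[^ACGU]", s)) stop("sequence contains residues outside {A,C,G,U}")
    return(Biostrings::RNAString(s))
  }
  stop("expected a single RNA sequence (RNAString or character scalar)")
}

#' Construct a LabelledSequenceSet
#'
#' @param sequences Named `RNAStringSet` (or character vector of sequences).
#' @param labels Named character vector of class labels, one per sequence id.
#' @return A [LabelledSequenceSet-class] whose `classSet` is the sorted set of
#'   distinct labels.
#' @export
labelledSequenceSet <- function(sequences, labels) {
  if (is.character(sequences))
    sequences <- Biostrings::RNAStringSet(.normalizeResidues(sequences))
  if (is.null(names(sequences))) stop("sequences must be named by id")
  if (is.null(names(labels))) stop("labels must be named by sequence id")
  labels <- labels[names(sequences)]
  if (anyNA(labels)) stop("every sequence id needs exactly one label")
  names(labels) <- names(sequences)
  new("LabelledSequenceSet", sequences = sequences,
      labels = labels, classSet = sort(unique(unname(labels))))
}

#' Construct a FeatureSet
#'
#' @param x Numeric matrix, samples in rows (ids as rownames), features in
#'   columns (manifest names as colnames).
#' @param labels Class labels, one per sample (named or in row order).
#' @return A [FeatureSet-class].
#' @export
featureSet <- function(x, labels) {
  if (is.null(colnames(x))) stop("feature columns must carry manifest names")
  if (!is.null(names(labels)) && !is.null(rownames(x))) labels <- labels[rownames(x)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(x)),
    colData = S4Vectors::DataFrame(label = as.character(labels), row.names = rownames(x)))
  new("FeatureSet", se)
}

# Euclidean-distance-ready copy of a feature matrix: the MFE column (kcal/mol
# scale) is standardized to zero mean / unit variance so it cannot dominate
# the frequency blocks; all other columns are left untouched.
.distanceReady <- function(X) {
  j <- which(colnames(X) == "MFE")
  if (length(j) == 1L) {
    v <- X[, j]
    s <- stats::sd(v)
    X[, j] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
  }
  X
}

.roundHalfUp <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
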