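# Sequence feature extraction: overlapping k-mer frequencies, per-frame
# reading-frame triplet frequencies, and the assembled 257-feature matrix.

#' Overlapping k-mer frequencies
#'
#' Counts all `M - k + 1` overlapping windows of length `k` and normalizes by
#' the window count, so the 4^k-vector sums to 1 regardless of sequence
#' length. Features are ordered lexicographically (A < C < G < U).
#'
#' @param seq A single RNA sequence (`RNAString` or character; T is accepted
#'   and read as U).
#' @param k Word length (the pipeline uses k = 3; generic in k).
#' @return Named numeric vector of length 4^k.
#' @export
kmerFrequencies <- function(seq, k = 3L) {
  x <- .asRnaString(seq)
  if (length(x) < k) stop("sequence length ", length(x), " < k = ", k)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
  cnt / sum(cnt)
}

#' Reading-frame triplet frequencies
#'
#' Splits the sequence into non-overlapping triplets from each of the three
#' possible start offsets (frames 1, 2, 3; trailing partial triplets are
#' dropped) and normalizes each frame's 64 counts by that frame's own triplet
#' count, so each row sums to 1.
#'
#' @param seq A single RNA sequence of length >= 5 (the shortest length for
#'   which frame 3 still holds a complete triplet).
#' @return 3 x 64 numeric matrix, rows `RF1`..`RF3`, columns the 64 triplets
#'   in lexicographic order.
#' @export
rfFrequencies <- function(seq) {
  x <- .asRnaString(seq)
  if (length(x) < 5L)
    stop("sequence length ", length(x), " < 5: frame 3 has no complete triplet")
  out <- t(vapply(1:3, function(f) {
    cnt <- Biostrings::oligonucleotideFrequency(
      Biostrings::subseq(x, start = f), width = 3L, step = 3L)
    cnt / sum(cnt)
  }, numeric(64)))
  rownames(out) <- paste0("RF", 1:3)
  out
}

#' Assemble the localization feature matrix
#'
#' Builds the full feature vector per sequence: 64 overlapping 3-mer
#' frequencies, 3 x 64 reading-frame triplet frequencies and one minimum
#' free energy scalar (257 features), or any named subset of these blocks
#' (the feature-combination ablations use the subsets).
#'
#' MFE values come either from the built-in simplified folder (the default)
#' or from imported RNAfold results; imported values must cover every
#' sequence id. MFE is used raw in kcal/mol by default; `mfePerNt = TRUE`
#' divides by sequence length.
#'
#' @param dataset A [LabelledSequenceSet-class].
#' @param features Character subset of `c("3mer", "3rf", "mfe")`.
#' @param mfe `NULL` to fold with the built-in model; a named numeric vector
#'   of energies; or a data.frame with `id` and `mfe` columns as returned by
#'   [readRnafoldOutput()].
#' @param energyModel [EnergyModel-class] for the built-in folder.
#' @param mfePerNt Divide MFE by sequence length (default `FALSE`).
#' @return A [FeatureSet-class]; its manifest (`featureManifest()`) names the
#'   columns `3mer:AAA` ... `RF3:UUU`, `MFE`.
#' @export
assembleFeatures <- function(dataset, features = c("3mer", "3rf", "mfe"),
                             mfe = NULL, energyModel = defaultEnergyModel(),
                             mfePerNt = FALSE) {
  stopifnot(is(dataset, "LabelledSequenceSet"))
  features <- match.arg(features, c("3mer", "3rf", "mfe"), several.ok = TRUE)
  seqs <- sequences(dataset)
  ids <- names(seqs)
  blocks <- list()
  if ("3mer" %in% features) {
    cnt <- Biostrings::oligonucleotideFrequency(seqs, width = 3L)
    blk <- cnt / rowSums(cnt)
    colnames(blk) <- paste0("3mer:", TRIPLETS)
    blocks <- c(blocks, list(blk))
  }
  if ("3rf" %in% features) {
    for (f in 1:3) {
      cnt <- Biostrings::oligonucleotideFrequency(
        Biostrings::subseq(seqs, start = f), width = 3L, step = 3L)
      blk <- cnt / rowSums(cnt)
      colnames(blk) <- paste0("RF", f, ":", TRIPLETS)
      blocks <- c(blocks, list(blk))
    }
  }
  if ("mfe" %in% features) {
    if (is.null(mfe)) {
      vals <- vapply(seq_along(seqs),
                     function(i) foldMFE(seqs[[i]], energyModel)$mfe, numeric(1))
      names(vals) <- ids
    } else {
      if (is.data.frame(mfe)) mfe <- setNames(mfe$mfe, mfe$id)
      missing <- setdiff(ids, names(mfe))
      if (length(missing))
        stop("imported MFE missing for id(s): ", paste(missing, collapse = ", "))
      vals <- as.numeric(mfe[ids])
    }
    if (mfePerNt) vals <- vals / Biostrings::width(seqs)
    blocks <- c(blocks, list(matrix(vals, ncol = 1, dimnames = list(NULL, "MFE"))))
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  featureSet(X, seqLabels(dataset))
}

#' Write a feature matrix to TSV
#'
#' One row per sequence, manifest names as the header, class label last.
#'
#' @param fs A [FeatureSet-class].
#' @param path Output path.
#' @export
writeFeatureTable <- function(fs, path) {
  df <- as.data.frame(featureMatrix(fs))
  df$label <- featureLabels(fs)
  utils::write.table(cbind(id = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureTable()]
#'
#' @param path Path to the TSV.
#' @return A [FeatureSet-class].
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- df$id
  labels <- df$label
  X <- as.matrix(df[, setdiff(colnames(df), c("id", "label")), drop = FALSE])
  rownames(X) <- ids
  featureSet(X, setNames(labels, ids))
}
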