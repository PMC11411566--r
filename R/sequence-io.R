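# Sequence and label import, dataset-construction filters, RNAfold interop.

#' Read and validate RNA sequences from FASTA
#'
#' Reads a multi-record FASTA file, normalizes residues (uppercase, T -> U)
#' and keeps only records that are pure A/C/G/U and at least `minLength` nt.
#' Rejected records are reported, not silently dropped.
#'
#' The default `minLength = 5` is the hard floor below which the third
#' reading frame has no complete triplet; for real lncRNA work a threshold of
#' 200 nt (the usual lncRNA definition) is recommended but not enforced.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param minLength Minimum accepted sequence length, in nt.
#' @return An `RNAStringSet` named by the first whitespace-delimited token of
#'   each header. `metadata(x)$rejected` holds a data.frame (id, reason) of
#'   rejected records.
#' @export
readFastaSequences <- function(path, minLength = 5L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- .normalizeResidues(as.character(raw))
  badAlpha <- grepl("[^ACGU]", res)
  tooShort <- !badAlpha & nchar(res) < minLength
  reason <- ifelse(badAlpha, "invalid_alphabet", ifelse(tooShort, "too_short", NA))
  rejected <- data.frame(id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- !(badAlpha | tooShort)
  if (!any(keep))
    stop("no sequences remain after filtering (", sum(badAlpha),
         " invalid alphabet, ", sum(tooShort), " too short)")
  out <- Biostrings::RNAStringSet(res[keep])
  names(out) <- ids[keep]
  S4Vectors::metadata(out)$rejected <- rejected
  out
}

#' Write sequences to FASTA
#'
#' @param x An `RNAStringSet` or [LabelledSequenceSet-class].
#' @param path Output path.
#' @export
writeFastaSequences <- function(x, path) {
  if (is(x, "LabelledSequenceSet")) x <- sequences(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Attach localization labels from a two-column TSV
#'
#' The label file has two tab-separated columns, `id` and `class`, no header.
#' Sequences without a label and labels without a sequence are reported with a
#' warning and excluded; an id labelled with two different classes is an
#' error.
#'
#' @param path Path to the TSV label file.
#' @param sequences `RNAStringSet` as returned by [readFastaSequences()].
#' @return A [LabelledSequenceSet-class] over the matched ids; `classSet` is
#'   the sorted set of distinct classes.
#' @export
readLabels <- function(path, sequences) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "class"), strip.white = TRUE)
  tab <- unique(tab)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("id(s) labelled with conflicting classes: ", paste(unique(dup), collapse = ", "))
  ids <- names(sequences)
  orphanLabels <- setdiff(tab$id, ids)
  if (length(orphanLabels))
    warning("label(s) for unknown sequence id(s), excluded: ",
            paste(orphanLabels, collapse = ", "))
  unlabelled <- setdiff(ids, tab$id)
  if (length(unlabelled))
    warning("sequence(s) without a label, excluded: ",
            paste(unlabelled, collapse = ", "))
  common <- intersect(ids, tab$id)
  if (!length(common)) stop("no sequence ids match the label file")
  labels <- setNames(tab$class, tab$id)[common]
  labelledSequenceSet(sequences[common], labels)
}

#' Drop classes below a minimum sample size
#'
#' Categories with fewer than `minCount` members are removed together with
#' their sequences (the dataset-construction rule: classes below 10 samples
#' are too small to model). Idempotent.
#'
#' @param dataset A [LabelledSequenceSet-class].
#' @param minCount Minimum class size retained (default 10).
#' @return The filtered [LabelledSequenceSet-class] with an updated classSet.
#' @export
filterMinClassSize <- function(dataset, minCount = 10L) {
  stopifnot(is(dataset, "LabelledSequenceSet"))
  cnt <- table(seqLabels(dataset))
  keepClasses <- names(cnt)[cnt >= minCount]
  if (!length(keepClasses)) stop("no classes remain at minCount = ", minCount)
  keep <- seqLabels(dataset) %in% keepClasses
  labelledSequenceSet(sequences(dataset)[keep], seqLabels(dataset)[keep])
}

#' Greedy redundancy reduction by shared-word containment
#'
#' A deterministic, self-contained stand-in for CD-HIT-style redundancy
#' removal at a fractional identity threshold. Sequences are sorted by
#' descending length (ties keep input order) and clustered greedily: a
#' sequence joins the first existing cluster whose representative shares at
#' least `identityThreshold` of the candidate's distinct `wordSize`-mers;
#' otherwise it founds a new cluster. Similarity of a shorter sequence to a
#' longer one is the fraction of the shorter sequence's distinct words that
#' also occur in the longer one (a containment, not alignment, identity —
#' exact CD-HIT parity is a non-goal). Cluster representatives are the
#' founders, i.e. the longest member of each cluster.
#'
#' @param x `RNAStringSet` or [LabelledSequenceSet-class].
#' @param identityThreshold Fraction in (0, 1]; default 0.80.
#' @param wordSize Word length for the containment similarity (default 5).
#' @param seed Unused (the procedure is fully deterministic); accepted for
#'   call-site compatibility.
#' @return Object of the same class containing only cluster representatives,
#'   in original input order. For an `RNAStringSet`,
#'   `metadata(x)$clusters` maps each input sequence id to its cluster id.
#' @export
greedyRedundancyFilter <- function(x, identityThreshold = 0.80, wordSize = 5L,
                                   seed = NULL) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be in (0, 1]")
  if (is(x, "LabelledSequenceSet")) {
    reps <- greedyRedundancyFilter(sequences(x), identityThreshold, wordSize)
    return(labelledSequenceSet(reps, seqLabels(x)[names(reps)]))
  }
  stopifnot(is(x, "RNAStringSet"))
  n <- length(x)
  if (n == 0L) return(x)
  km <- Biostrings::oligonucleotideFrequency(x, width = wordSize) > 0
  nWords <- rowSums(km)
  ord <- order(-Biostrings::width(x))  # stable: ties keep input order
  clusterOf <- integer(n)
  repIdx <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    if (length(repIdx) && nWords[i] > 0) {
      shared <- as.vector(km[repIdx, , drop = FALSE] %*% km[i, ])
      sims <- shared / nWords[i]
      hit <- which(sims >= identityThreshold)
      if (length(hit)) {
        clusterOf[i] <- hit[1L]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      repIdx <- c(repIdx, i)
      clusterOf[i] <- length(repIdx)
    }
  }
  out <- x[sort(repIdx)]
  S4Vectors::metadata(out)$clusters <- setNames(clusterOf, names(x))
  out
}

#' Read RNAfold-style text output
#'
#' Parses the plain-text layout produced by RNAfold: a `>` header line, the
#' sequence line, then the dot-bracket structure followed by the free energy
#' in parentheses, e.g. `(((...))) ( -1.20)`.
#'
#' @param path Path to the RNAfold output file.
#' @return data.frame with columns `id`, `sequence` (normalized to RNA),
#'   `structure`, `mfe` (kcal/mol).
#' @export
readRnafoldOutput <- function(path) {
  if (!file.exists(path)) stop("RNAfold output not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records (no '>' headers) in ", path)
  recs <- lapply(seq_along(hdr), function(r) {
    from <- hdr[r]
    to <- if (r < length(hdr)) hdr[r + 1] - 1L else length(lines)
    id <- sub("\\s.*$", "", sub("^>", "", lines[from]))
    if (to - from < 2L) stop("record '", id, "': expected sequence and structure lines")
    seq <- .normalizeResidues(trimws(lines[from + 1L]))
    structLine <- trimws(lines[from + 2L])
    m <- regmatches(structLine,
                    regexec("^([.()]+)\\s*\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)$", structLine))[[1]]
    if (length(m) != 3L)
      stop("record '", id, "': cannot parse structure/energy line: ", structLine)
    db <- m[2]
    mfe <- as.numeric(m[3])
    if (nchar(db) != nchar(seq))
      stop("record '", id, "': structure length ", nchar(db),
           " != sequence length ", nchar(seq))
    msg <- .dotBracketProblem(db)
    if (!is.null(msg)) stop("record '", id, "': ", msg)
    data.frame(id = id, sequence = seq, structure = db, mfe = mfe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
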