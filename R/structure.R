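# Secondary structure: simplified MFE folding, stem/loop/junction window
# classification, and triplet-frequency tables per substructure.

#' Default simplified energy model
#'
#' Small-integer parameters chosen for transparency and testability, NOT the
#' Turner thermodynamic set: stacking -3 kcal/mol for CG/GC on CG/GC, -2 for
#' stacks mixing in AU/UA, -1 for any stack involving a GU/UG wobble;
#' hairpin +3 (loops below 3 nt forbidden); bulge and interior loops
#' +2 + 0.5 per unpaired nt; multiloop +4 + 1 per enclosed branch. For
#' biological fidelity, import RNAfold output instead
#' ([readRnafoldOutput()]).
#'
#' @param maxInterior Cap on unpaired nucleotides in bulge/interior loops.
#' @param allowGU Allow GU/UG wobble pairs (default `TRUE`).
#' @return An [EnergyModel-class].
#' @export
defaultEnergyModel <- function(maxInterior = 30L, allowGU = TRUE) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  isWobble <- pairs %in% c("GU", "UG")
  isStrong <- pairs %in% c("CG", "GC")
  st <- matrix(0, 6, 6, dimnames = list(pairs, pairs))
  for (p in 1:6) for (q in 1:6) {
    st[p, q] <- if (isWobble[p] || isWobble[q]) -1
                else if (isStrong[p] && isStrong[q]) -3
                else -2
  }
  new("EnergyModel", stacking = st, hairpinPenalty = 3,
      bulgeBase = 2, bulgeSlope = 0.5, interiorBase = 2, interiorSlope = 0.5,
      multiBase = 4, multiBranch = 1,
      minHairpin = 3L, maxInterior = as.integer(maxInterior),
      allowGU = isTRUE(allowGU))
}

#' Fold a sequence to its minimum free energy structure
#'
#' Interval dynamic program over the loop decomposition (stacking, bulge,
#' interior, hairpin, multi-branch) of the supplied [EnergyModel-class], with
#' traceback to a nested dot-bracket. A sequence admitting no legal pair
#' returns energy 0 and an all-dot structure; the returned energy is never
#' positive (the open chain scores 0).
#'
#' @param seq A single RNA sequence.
#' @param model An [EnergyModel-class].
#' @return List with `mfe` (kcal/mol) and `structure`
#'   (a [DotBracketStructure-class], source `"builtin"`).
#' @export
foldMFE <- function(seq, model = defaultEnergyModel()) {
  x <- .asRnaString(seq)
  res <- foldMfeCpp(as.character(x), model@stacking, model@hairpinPenalty,
                    model@bulgeBase, model@bulgeSlope,
                    model@interiorBase, model@interiorSlope,
                    model@multiBase, model@multiBranch,
                    model@minHairpin, model@maxInterior, model@allowGU)
  list(mfe = res$mfe,
       structure = new("DotBracketStructure", structure = res$structure,
                       source = "builtin"))
}

#' Fold every sequence of a set
#'
#' @param x `RNAStringSet` or [LabelledSequenceSet-class].
#' @param model An [EnergyModel-class].
#' @return data.frame with columns `id`, `sequence`, `structure`, `mfe` (the
#'   same layout as [readRnafoldOutput()], so the two backends are
#'   interchangeable downstream).
#' @export
foldSequences <- function(x, model = defaultEnergyModel()) {
  if (is(x, "LabelledSequenceSet")) x <- sequences(x)
  stopifnot(is(x, "RNAStringSet"))
  res <- lapply(seq_along(x), function(i) foldMFE(x[[i]], model))
  data.frame(id = names(x),
             sequence = as.character(x),
             structure = vapply(res, function(r) r$structure@structure, character(1)),
             mfe = vapply(res, function(r) r$mfe, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score a given structure under an energy model
#'
#' Recomputes the energy of an explicit dot-bracket structure by its loop
#' decomposition — the same scoring the folder minimizes. Used for
#' self-consistency (the traceback structure must score exactly the returned
#' MFE); exported because it is also handy for comparing imported structures
#' under the built-in model.
#'
#' @param seq A single RNA sequence.
#' @param structure Dot-bracket string or [DotBracketStructure-class].
#' @param model An [EnergyModel-class].
#' @return Energy in kcal/mol.
#' @export
structureEnergy <- function(seq, structure, model = defaultEnergyModel()) {
  x <- as.character(.asRnaString(seq))
  db <- if (is(structure, "DotBracketStructure")) structure@structure else structure
  .assertDotBracket(db)
  if (nchar(db) != nchar(x)) stop("structure length != sequence length")
  v <- strsplit(db, "")[[1]]
  n <- length(v)
  pairOf <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairOf[i] <- j; pairOf[j] <- i
    }
  }
  bases <- strsplit(x, "")[[1]]
  pairs <- rownames(model@stacking)
  ptype <- function(i, j) {
    p <- paste0(bases[i], bases[j])
    m <- match(p, pairs)
    if (is.na(m)) stop("illegal base pair ", p, " at (", i, ",", j, ")")
    if (!model@allowGU && p %in% c("GU", "UG")) stop("GU pair present but disallowed")
    m
  }
  # children = directly enclosed pairs of (i, j); i = 0 means external level
  childrenOf <- function(i, j) {
    kids <- list()
    p <- i + 1L
    while (p < j) {
      if (v[p] == "(") {
        kids <- c(kids, list(c(p, pairOf[p])))
        p <- pairOf[p] + 1L
      } else p <- p + 1L
    }
    kids
  }
  scorePair <- function(i, j) {
    kids <- childrenOf(i, j)
    if (length(kids) == 0L) {
      loop <- j - i - 1L
      if (loop < model@minHairpin) stop("hairpin loop of size ", loop, " below minimum")
      return(model@hairpinPenalty)
    }
    if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      g1 <- k - i - 1L; g2 <- j - l - 1L
      inner <- scorePair(k, l)
      if (g1 == 0L && g2 == 0L)
        return(model@stacking[ptype(i, j), ptype(k, l)] + inner)
      if (g1 == 0L || g2 == 0L)
        return(model@bulgeBase + model@bulgeSlope * (g1 + g2) + inner)
      return(model@interiorBase + model@interiorSlope * (g1 + g2) + inner)
    }
    ptype(i, j)  # validates the closing pair
    model@multiBase + model@multiBranch * length(kids) +
      sum(vapply(kids, function(kl) scorePair(kl[1], kl[2]), numeric(1)))
  }
  ext <- childrenOf(0L, n + 1L)
  sum(vapply(ext, function(kl) {
    ptype(kl[1], kl[2])
    scorePair(kl[1], kl[2])
  }, numeric(1)))
}

#' Classify structure windows as stem, loop or junction
#'
#' Slides a 3-character window over the dot-bracket string: a window of three
#' dots is a loop, three brackets of the same direction are a stem, and any
#' mixed window (including `(.)`, `..(` and `)..`) is a junction. Window `i`
#' covers structure positions `i..i+2`, so a structure of length M yields
#' M - 2 categories.
#'
#' @param structure Dot-bracket string or [DotBracketStructure-class].
#' @return Character vector of length M - 2 over
#'   `c("stem", "loop", "junction")`.
#' @export
classifyWindows <- function(structure) {
  db <- if (is(structure, "DotBracketStructure")) structure@structure else structure
  .assertDotBracket(db)
  v <- strsplit(db, "")[[1]]
  n <- length(v)
  if (n < 3L) return(character(0))
  a <- v[1:(n - 2)]; b <- v[2:(n - 1)]; c <- v[3:n]
  out <- rep("junction", n - 2L)
  out[a == "." & b == "." & c == "."] <- "loop"
  out[(a == "(" & b == "(" & c == "(") | (a == ")" & b == ")" & c == ")")] <- "stem"
  out
}

#' Triplet frequencies per secondary-structure substructure
#'
#' For every 3-nt window, pairs the sequence triplet with the window's
#' substructure category ([classifyWindows()]) and tabulates, per category,
#' the percentage of windows carrying each of the 64 triplets. Each category
#' column is a distribution over 64 triplets summing to 100%; the baseline
#' column is the uniform expectation 100/64 = 1.5625%.
#'
#' @param folds data.frame with columns `sequence` and `structure` (from
#'   [foldSequences()] or [readRnafoldOutput()]).
#' @return data.frame with columns `triplex`, `junction`, `loop`, `stem`,
#'   `baseline` (all percentages). Categories with zero windows report zero
#'   frequencies and are listed in `attr(x, "emptyCategories")`.
#' @export
triplexSubstructureFrequencies <- function(folds) {
  if (!is.data.frame(folds) || !all(c("sequence", "structure") %in% colnames(folds)))
    stop("expected a data.frame with 'sequence' and 'structure' columns")
  if (nrow(folds) == 0L) stop("empty input: no sequence/structure pairs")
  if (any(nchar(folds$sequence) != nchar(folds$structure)))
    stop("structure length must equal sequence length for every record")
  cats <- c("junction", "loop", "stem")
  counts <- matrix(0L, nrow = 64, ncol = 3, dimnames = list(TRIPLETS, cats))
  for (r in seq_len(nrow(folds))) {
    s <- .normalizeResidues(folds$sequence[r])
    n <- nchar(s)
    if (n < 3L) next
    code <- match(strsplit(s, "")[[1]], RNA_BASES) - 1L
    if (anyNA(code)) stop("record ", r, ": sequence outside {A,C,G,U}")
    trip <- 16L * code[1:(n - 2)] + 4L * code[2:(n - 1)] + code[3:n] + 1L
    cat <- classifyWindows(folds$structure[r])
    tab <- table(factor(trip, levels = 1:64), factor(cat, levels = cats))
    counts <- counts + unclass(tab)
  }
  totals <- colSums(counts)
  pct <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  empty <- cats[totals == 0]
  out <- data.frame(triplex = TRIPLETS, junction = pct[, "junction"],
                    loop = pct[, "loop"], stem = pct[, "stem"],
                    baseline = 100 / 64, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "emptyCategories") <- empty
  attr(out, "windowCounts") <- totals
  out
}

#' Pooled overlapping triplet frequencies of a sequence set
#'
#' @param dataset [LabelledSequenceSet-class] or `RNAStringSet`.
#' @return Named numeric vector of 64 percentages summing to 100.
#' @export
sequenceTriplexFrequencies <- function(dataset) {
  x <- if (is(dataset, "LabelledSequenceSet")) sequences(dataset) else dataset
  stopifnot(is(x, "RNAStringSet"))
  if (length(x) == 0L) stop("empty sequence set")
  cnt <- colSums(Biostrings::oligonucleotideFrequency(x, width = 3L))
  100 * cnt / sum(cnt)
}
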