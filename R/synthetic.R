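# Synthetic labelled sequence sets with planted class-specific triplet
# enrichments and a configurable imbalance profile, so the whole pipeline is
# testable without any external database.

#' Generator configuration
#'
#' Sequences are generated triplet-wise: each successive non-overlapping
#' triplet is drawn from the 64-triplet distribution proportional to the
#' product of background base probabilities, with the class's biased
#' triplexes multiplied by their enrichment factor rho and renormalized.
#' Triplet-wise generation puts the planted signal into the overlapping
#' 3-mer features and, at full strength, the frame-1 reading-frame block,
#' with frames 2/3 receiving attenuated signal — mimicking real data where
#' the same triplex can rank differently per frame.
#'
#' @param classes List of per-class specs: `list(name =, count =, bias =)`
#'   where `bias` is a named numeric vector of enrichment factors rho >= 1
#'   over triplet names (may be empty).
#' @param lengthRange Two integers `[Lmin, Lmax]`; each sequence length is
#'   uniform in the range, floored to a multiple of 3, plus a uniform 0-2 nt
#'   tail drawn from the background.
#' @param background Four base probabilities (A, C, G, U) summing to 1.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated config list of class `generatorConfig`.
#' @export
generatorConfig <- function(classes, lengthRange = c(200L, 600L),
                            background = rep(0.25, 4), seed = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1)
  for (cl in classes) {
    if (!all(c("name", "count") %in% names(cl))) stop("each class needs name and count")
    if (cl$count < 1) stop("class counts must be >= 1")
    bias <- cl$bias
    if (!is.null(bias) && length(bias)) {
      if (any(bias < 1)) stop("enrichment factors rho must be >= 1")
      if (!all(names(bias) %in% TRIPLETS)) stop("bias names must be RNA triplets")
    }
  }
  if (length(lengthRange) != 2 || lengthRange[1] > lengthRange[2] || lengthRange[1] < 5)
    stop("lengthRange must be [Lmin, Lmax] with 5 <= Lmin <= Lmax")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stop("background must be 4 positive base probabilities summing to 1")
  structure(list(classes = classes, lengthRange = as.integer(lengthRange),
                 background = setNames(background, RNA_BASES),
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Per-class triplet sampling distributions of a config
#'
#' @param config A `generatorConfig`.
#' @return Named list of 64-probability vectors, one per class.
#' @export
generatorTripletDistributions <- function(config) {
  bg <- config$background
  base <- vapply(TRIPLETS, function(t) {
    b <- strsplit(t, "")[[1]]
    bg[b[1]] * bg[b[2]] * bg[b[3]]
  }, numeric(1))
  out <- lapply(config$classes, function(cl) {
    p <- base
    if (!is.null(cl$bias) && length(cl$bias)) p[names(cl$bias)] <- p[names(cl$bias)] * cl$bias
    p / sum(p)
  })
  names(out) <- vapply(config$classes, `[[`, character(1), "name")
  out
}

#' Generate a labelled sequence set
#'
#' @param config A `generatorConfig`.
#' @return A [LabelledSequenceSet-class]; ids are `<class>_<index>`.
#' @export
generateSequenceSet <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  dists <- generatorTripletDistributions(config)
  bg <- config$background
  lr <- config$lengthRange
  seqs <- character(0); labels <- character(0); ids <- character(0)
  for (cl in config$classes) {
    p <- dists[[cl$name]]
    for (i in seq_len(cl$count)) {
      L0 <- lr[1] + sample.int(lr[2] - lr[1] + 1L, 1L) - 1L
      nTrip <- L0 %/% 3L
      tailLen <- sample(0:2, 1L)
      trip <- sample.int(64L, nTrip, replace = TRUE, prob = p)
      tail <- if (tailLen > 0) paste(sample(RNA_BASES, tailLen, replace = TRUE, prob = bg),
                                     collapse = "") else ""
      seqs <- c(seqs, paste0(paste(TRIPLETS[trip], collapse = ""), tail))
      ids <- c(ids, sprintf("%s_%03d", cl$name, i))
      labels <- c(labels, cl$name)
    }
  }
  names(seqs) <- ids
  labelledSequenceSet(seqs, setNames(labels, ids))
}

#' Planted triplexes of the 5-class benchmark
#'
#' @return Named list mapping each benchmark class to its two enriched
#'   triplexes.
#' @export
benchmarkPlantedTriplexes <- function() {
  pool <- c("ACA", "AUA", "AGA", "UCA", "GGU", "UAU", "CGG", "GGC", "UUU", "CCC")
  classes <- c("nucleus", "cytoplasm", "ribosome", "cytosol", "exosome")
  setNames(split(pool, rep(seq_along(classes), each = 2)), classes)
}

#' Five-class imbalanced benchmark
#'
#' A fixed imbalanced benchmark mirroring the shape of real localization
#' data: class counts (nucleus 200, cytoplasm 120, ribosome 45, cytosol 30,
#' exosome 8; majority:minority 25:1), lengths 200-600 nt, each class
#' enriched rho = 6 in two class-specific triplexes (disjoint across
#' classes; see [benchmarkPlantedTriplexes()]).
#'
#' @param seed Integer seed.
#' @return A [LabelledSequenceSet-class].
#' @export
benchmark5Class <- function(seed = 1L) {
  planted <- benchmarkPlantedTriplexes()
  counts <- c(nucleus = 200L, cytoplasm = 120L, ribosome = 45L,
              cytosol = 30L, exosome = 8L)
  classes <- lapply(names(counts), function(nm)
    list(name = nm, count = counts[[nm]],
         bias = setNames(rep(6, 2), planted[[nm]])))
  generateSequenceSet(generatorConfig(classes, lengthRange = c(200L, 600L),
                                      seed = seed))
}
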