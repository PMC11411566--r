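# S4 class definitions, in dependency order.

#' Labelled set of RNA sequences
#'
#' Couples an [Biostrings::RNAStringSet] with one localization label per
#' sequence and a fixed, lexicographically sorted class set. The class-set
#' order is used for all downstream tie-breaking (prediction ties, majority
#' votes), so it is enforced at construction and never reordered.
#'
#' @slot sequences An `RNAStringSet`; every sequence is at least 5 nt (the
#'   shortest length for which all three reading frames hold a full triplet).
#' @slot labels Named character vector, one class name per sequence id.
#' @slot classSet Sorted character vector of distinct class names.
#' @export
setClass("LabelledSequenceSet",
  slots = c(sequences = "RNAStringSet", labels = "character", classSet = "character"))

setValidity("LabelledSequenceSet", function(object) {
  seqs <- object@sequences
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) return("sequence ids must be unique and non-NULL")
  if (length(seqs) && any(Biostrings::width(seqs) < 5))
    return("all sequences must be at least 5 nt")
  if (!setequal(names(object@labels), ids) || length(object@labels) != length(seqs))
    return("labels must be named by sequence id, exactly one per sequence")
  if (!all(object@labels %in% object@classSet))
    return("every label must be a member of classSet")
  if (is.unsorted(object@classSet) || anyDuplicated(object@classSet))
    return("classSet must be sorted and duplicate-free")
  chars <- unique(unlist(strsplit(as.character(seqs), "")))
  if (length(chars) && !all(chars %in% c("A", "C", "G", "U")))
    return("sequences must be over the alphabet {A,C,G,U}")
  TRUE
})

#' Simplified nearest-neighbour energy model for RNA folding
#'
#' Parameterizes the folding recursion: stacking energies per pair-on-pair
#' combination, flat hairpin penalty, linear bulge/interior penalties in loop
#' size, and an affine multiloop penalty (base + per-branch). The defaults
#' (see [defaultEnergyModel()]) are small integers chosen so exhaustive
#' enumeration can verify the dynamic program; they are deliberately not the
#' Turner thermodynamic parameters.
#'
#' @slot stacking 6x6 numeric matrix (pairs AU, UA, CG, GC, GU, UG), all
#'   entries <= 0; `stacking[p, q]` is the energy of pair q stacked directly
#'   inside pair p.
#' @slot hairpinPenalty,bulgeBase,bulgeSlope,interiorBase,interiorSlope
#'   Non-negative loop penalties (kcal/mol); bulge/interior cost is
#'   `base + slope * size`.
#' @slot multiBase,multiBranch Affine multiloop penalty: `multiBase +
#'   multiBranch * (number of enclosed branch helices)`, branches >= 2.
#' @slot minHairpin Minimum unpaired hairpin loop size (default 3).
#' @slot maxInterior Cap on total unpaired nucleotides in a bulge/interior
#'   loop (stacking is never capped); bounds the DP cost at O(n^2 cap^2).
#' @slot allowGU Whether GU/UG wobble pairs may form.
#' @export
setClass("EnergyModel",
  slots = c(stacking = "matrix", hairpinPenalty = "numeric",
            bulgeBase = "numeric", bulgeSlope = "numeric",
            interiorBase = "numeric", interiorSlope = "numeric",
            multiBase = "numeric", multiBranch = "numeric",
            minHairpin = "integer", maxInterior = "integer",
            allowGU = "logical"))

setValidity("EnergyModel", function(object) {
  if (!identical(dim(object@stacking), c(6L, 6L))) return("stacking must be 6x6")
  if (any(object@stacking > 0)) return("stacking energies must be <= 0")
  pen <- c(object@hairpinPenalty, object@bulgeBase, object@bulgeSlope,
           object@interiorBase, object@interiorSlope,
           object@multiBase, object@multiBranch)
  if (any(pen < 0)) return("loop penalties must be >= 0")
  if (object@minHairpin < 3L) return("minHairpin must be >= 3")
  TRUE
})

#' Dot-bracket secondary structure
#'
#' A balanced, pseudoknot-free dot-bracket string together with its origin
#' (built-in folder or imported RNAfold output).
#'
#' @slot structure Character scalar over `(`, `)`, `.`.
#' @slot source `"builtin"` or `"imported"`.
#' @export
setClass("DotBracketStructure",
  slots = c(structure = "character", source = "character"))

setValidity("DotBracketStructure", function(object) {
  if (length(object@structure) != 1L) return("structure must be a single string")
  if (!object@source %in% c("builtin", "imported")) return("source must be builtin or imported")
  msg <- .dotBracketProblem(object@structure)
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Feature container for localization prediction
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with features in rows
#' (named by the feature manifest, e.g. `3mer:ACA`, `RF2:AUA`, `MFE`) and
#' sequences in columns; `colData(x)$label` carries the class labels.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'label' column")
  if (is.null(rownames(object))) return("feature rows must be named (manifest)")
  TRUE
})

#' Oversampling plan
#'
#' Per-class target counts plus the oversampler configuration used to reach
#' them. Targets below current counts mean "leave the class alone".
#'
#' @slot targetCounts Named integer vector of per-class target sizes.
#' @slot smoteK Minority-neighbour count used for interpolation (default 5).
#' @slot dangerM Neighbourhood size for danger detection / ADASYN ratios
#'   (default 5).
#' @slot method Named character vector, `"borderline-smote"` or `"adasyn"`
#'   per class.
#' @slot seed Integer seed controlling all oversampling randomness.
#' @export
setClass("BalancingPlan",
  slots = c(targetCounts = "integer", smoteK = "integer", dangerM = "integer",
            method = "character", seed = "integer"))

setValidity("BalancingPlan", function(object) {
  if (is.null(names(object@targetCounts))) return("targetCounts must be named by class")
  if (!all(object@method %in% c("borderline-smote", "adasyn")))
    return("method must be 'borderline-smote' or 'adasyn'")
  if (!setequal(names(object@method), names(object@targetCounts)))
    return("method must be named by the same classes as targetCounts")
  if (object@smoteK < 1L || object@dangerM < 1L) return("smoteK and dangerM must be >= 1")
  TRUE
})

#' Synthetic samples produced by an oversampler
#'
#' Every synthetic point is an exact convex interpolation
#' `parentA + u * (parentB - parentA)` between two recorded real minority
#' parents, which keeps every per-block normalization of the parents intact.
#'
#' @slot features Numeric matrix, one synthetic sample per row.
#' @slot parentA,parentB Integer row indices of the parents in the matrix the
#'   oversampler was given.
#' @slot u Interpolation fractions in `[0, 1]`.
#' @slot classLabel Assigned class (one per sample).
#' @slot uncertainty Ensemble vote entropy in nats (`NA` until
#'   [uncertaintyFilter()] has scored the samples).
#' @export
setClass("SyntheticSampleSet",
  slots = c(features = "matrix", parentA = "integer", parentB = "integer",
            u = "numeric", classLabel = "character", uncertainty = "numeric"))

setValidity("SyntheticSampleSet", function(object) {
  n <- nrow(object@features)
  lens <- c(length(object@parentA), length(object@parentB), length(object@u),
            length(object@classLabel), length(object@uncertainty))
  if (!all(lens == n)) return("all provenance slots must have one entry per sample")
  if (n && (any(object@u < 0) || any(object@u > 1))) return("u must lie in [0, 1]")
  TRUE
})

#' Boosted multiclass model
#'
#' An ordered list of depth-limited weighted decision trees with their round
#' coefficients alpha_t. Rounds with non-positive alpha are never stored:
#' training stops at the positivity boundary of the multiclass coefficient.
#'
#' @slot trees List of flat node tables (feature, threshold, left, right, pred).
#' @slot alphas Positive round coefficients, natural-log scale.
#' @slot classSet Ordered class names (k >= 2); prediction ties resolve to the
#'   first class in this order.
#' @slot config Training configuration and diagnostics (depth, Tmax, epsilon
#'   floor, per-round weighted errors, post-renormalization weight sums, seed,
#'   feature count).
#' @export
setClass("BoostModel",
  slots = c(trees = "list", alphas = "numeric", classSet = "character",
            config = "list"))

setValidity("BoostModel", function(object) {
  if (length(object@trees) != length(object@alphas))
    return("one alpha per stored round")
  if (length(object@alphas) && any(object@alphas <= 0))
    return("all stored alphas must be > 0")
  if (length(object@classSet) < 2L) return("at least two classes required")
  TRUE
})

#' Performance report
#'
#' Per-class one-vs-rest counts and derived Sn/Sp/MCC (optionally AUC), a k x k
#' confusion matrix, and the single overall accuracy.
#'
#' @slot confusion k x k integer matrix, true classes in rows.
#' @slot perClass data.frame with one row per class: TP, FN, FP, TN, Sn, Sp,
#'   MCC, AUC.
#' @slot acc Overall accuracy, `trace(confusion) / sum(confusion)`.
#' @export
setClass("MetricsReport",
  slots = c(confusion = "matrix", perClass = "data.frame", acc = "numeric"))

setValidity("MetricsReport", function(object) {
  need <- c("TP", "FN", "FP", "TN", "Sn", "Sp", "MCC", "AUC")
  if (!all(need %in% colnames(object@perClass)))
    return("perClass must contain TP, FN, FP, TN, Sn, Sp, MCC, AUC")
  tot <- sum(object@confusion)
  rows <- object@perClass
  if (nrow(rows) && any(rows$TP + rows$FN + rows$FP + rows$TN != tot))
    return("per-class one-vs-rest counts must sum to the total sample count")
  TRUE
})

#' F-score feature ranking
#'
#' Non-negative per-feature F-scores (between-class over within-class scatter)
#' with a deterministic descending rank order (ties broken by feature index).
#'
#' @slot scores Named non-negative numeric vector.
#' @slot ranking Integer permutation of the features, best first.
#' @export
setClass("FScoreRanking", slots = c(scores = "numeric", ranking = "integer"))

setValidity("FScoreRanking", function(object) {
  if (any(object@scores < 0)) return("F-scores must be non-negative")
  if (!setequal(object@ranking, seq_along(object@scores)))
    return("ranking must be a permutation of the features")
  TRUE
})
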