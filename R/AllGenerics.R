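# Generics and accessors.

#' @rdname LabelledSequenceSet-class
#' @param x,object A `LabelledSequenceSet`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname LabelledSequenceSet-class
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))

#' @rdname LabelledSequenceSet-class
#' @export
setGeneric("classSet", function(x) standardGeneric("classSet"))

#' @rdname LabelledSequenceSet-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname FeatureSet-class
#' @param x A `FeatureSet`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureManifest", function(x) standardGeneric("featureManifest"))

#' @export
setGeneric("predict")

#' @rdname LabelledSequenceSet-class
#' @export
setMethod("sequences", "LabelledSequenceSet", function(x) x@sequences)

#' @rdname LabelledSequenceSet-class
#' @export
setMethod("seqLabels", "LabelledSequenceSet",
  function(x) x@labels[names(x@sequences)])

#' @rdname LabelledSequenceSet-class
#' @export
setMethod("classSet", "LabelledSequenceSet", function(x) x@classSet)

#' @rdname LabelledSequenceSet-class
#' @export
setMethod("classCounts", "LabelledSequenceSet", function(x) {
  lab <- factor(seqLabels(x), levels = x@classSet)
  table(lab, dnn = NULL)
})

#' @rdname LabelledSequenceSet-class
#' @export
setMethod("length", "LabelledSequenceSet", function(x) length(x@sequences))

#' @rdname LabelledSequenceSet-class
#' @param i Index (ids, logical, or positions).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "LabelledSequenceSet", function(x, i, j, ..., drop = TRUE) {
  seqs <- x@sequences[i]
  labelledSequenceSet(seqs, x@labels[names(seqs)])
})

setMethod("show", "LabelledSequenceSet", function(object) {
  cat("LabelledSequenceSet with", length(object), "sequences,",
      length(object@classSet), "classes\n")
  print(classCounts(object))
  w <- Biostrings::width(object@sequences)
  if (length(w)) cat("lengths:", min(w), "-", max(w), "nt\n")
})

#' @rdname FeatureSet-class
#' @export
setMethod("featureMatrix", "FeatureSet",
  function(x) t(SummarizedExperiment::assay(x, "features")))

#' @rdname FeatureSet-class
#' @export
setMethod("featureLabels", "FeatureSet",
  function(x) setNames(as.character(SummarizedExperiment::colData(x)$label), colnames(x)))

#' @rdname FeatureSet-class
#' @export
setMethod("featureManifest", "FeatureSet", function(x) rownames(x))

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", ncol(object), "sequences x", nrow(object), "features\n")
  cat("manifest:", paste(head(rownames(object), 3), collapse = ", "),
      "...", rownames(object)[nrow(object)], "\n")
  print(table(SummarizedExperiment::colData(object)$label))
})

setMethod("show", "BoostModel", function(object) {
  cat("BoostModel:", length(object@alphas), "rounds,",
      length(object@classSet), "classes (",
      paste(object@classSet, collapse = ", "), ")\n")
  cat("tree depth:", object@config$depth,
      "| alpha range:", signif(range(object@alphas), 4), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport — overall ACC:", sprintf("%.2f%%", 100 * object@acc), "\n")
  tab <- object@perClass
  tab$Sn <- round(100 * tab$Sn, 2)
  tab$Sp <- round(100 * tab$Sp, 2)
  tab$MCC <- round(tab$MCC, 3)
  tab$AUC <- round(tab$AUC, 3)
  print(tab[, c("Sn", "Sp", "MCC", "AUC")])
})

setMethod("show", "BalancingPlan", function(object) {
  cat("BalancingPlan (smoteK =", object@smoteK, ", dangerM =", object@dangerM, ")\n")
  print(data.frame(target = object@targetCounts,
                   method = object@method[names(object@targetCounts)]))
})

setMethod("show", "SyntheticSampleSet", function(object) {
  cat("SyntheticSampleSet:", nrow(object@features), "samples\n")
  if (nrow(object@features)) print(table(object@classLabel))
})

setMethod("show", "FScoreRanking", function(object) {
  cat("FScoreRanking over", length(object@scores), "features; top 5:\n")
  top <- object@ranking[seq_len(min(5, length(object@ranking)))]
  print(round(object@scores[top], 4))
})

setMethod("show", "DotBracketStructure", function(object) {
  s <- object@structure
  cat("DotBracketStructure (", object@source, ", ", nchar(s), " nt)\n", sep = "")
  cat(if (nchar(s) > 60) paste0(substr(s, 1, 60), "...") else s, "\n")
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel: minHairpin", object@minHairpin,
      "| interior cap", object@maxInterior,
      "| GU pairs", if (object@allowGU) "allowed" else "disallowed", "\n")
  cat("stacking range:", paste(range(object@stacking), collapse = " to "),
      "kcal/mol; hairpin penalty", object@hairpinPenalty, "\n")
})
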