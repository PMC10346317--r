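#' Accessors for sdplpet objects
#'
#' Small accessor generics for the package's S4 classes: the sparse system
#' matrix and geometry of a \linkS4class{SystemModel}, the ray subsets of a
#' \linkS4class{SubsetPartition}, the masks and true contrasts of an
#' \linkS4class{ROISet}, and the estimate and objective trace of a
#' \linkS4class{ReconResult}.
#'
#' @param object an object of the documented class.
#' @return The slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("systemMatrix", function(object) standardGeneric("systemMatrix"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("nAngles", function(object) standardGeneric("nAngles"))
#' @rdname accessors
#' @export
setGeneric("imageSize", function(object) standardGeneric("imageSize"))
#' @rdname accessors
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))
#' @rdname accessors
#' @export
setGeneric("raySubsets", function(object) standardGeneric("raySubsets"))
#' @rdname accessors
#' @export
setGeneric("nSubsets", function(object) standardGeneric("nSubsets"))
#' @rdname accessors
#' @export
setGeneric("regionalRois", function(object) standardGeneric("regionalRois"))
#' @rdname accessors
#' @export
setGeneric("crcRois", function(object) standardGeneric("crcRois"))
#' @rdname accessors
#' @export
setGeneric("backgroundRoi", function(object) standardGeneric("backgroundRoi"))
#' @rdname accessors
#' @export
setGeneric("trueContrast", function(object) standardGeneric("trueContrast"))
#' @rdname accessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))
#' @rdname accessors
#' @export
setGeneric("objectiveHistory",
           function(object) standardGeneric("objectiveHistory"))
#' @rdname accessors
#' @export
setGeneric("similarityWeights",
           function(object) standardGeneric("similarityWeights"))
#' @rdname accessors
#' @export
setGeneric("meanSimilarity",
           function(object) standardGeneric("meanSimilarity"))
#' @rdname accessors
#' @export
setGeneric("controlValues", function(object) standardGeneric("controlValues"))

#' @rdname accessors
setMethod("systemMatrix", "SystemModel", function(object) object@H)
#' @rdname accessors
setMethod("nBins", "SystemModel", function(object) object@nBins)
#' @rdname accessors
setMethod("nAngles", "SystemModel", function(object) object@nAngles)
#' @rdname accessors
setMethod("imageSize", "SystemModel", function(object) object@imageSize)
#' @rdname accessors
setMethod("viewAngles", "SystemModel", function(object) object@angles)
#' @rdname accessors
setMethod("raySubsets", "SubsetPartition", function(object) object@rays)
#' @rdname accessors
setMethod("nSubsets", "SubsetPartition", function(object) object@nSubsets)
#' @rdname accessors
setMethod("regionalRois", "ROISet", function(object) object@regional)
#' @rdname accessors
setMethod("crcRois", "ROISet", function(object) object@crc)
#' @rdname accessors
setMethod("backgroundRoi", "ROISet", function(object) object@background)
#' @rdname accessors
setMethod("trueContrast", "ROISet", function(object) object@trueContrast)
#' @rdname accessors
setMethod("estimate", "ReconResult", function(object) object@estimate)
#' @rdname accessors
setMethod("objectiveHistory", "ReconResult", function(object) object@history)
#' @rdname accessors
setMethod("similarityWeights", "SimilarityField", function(object) object@W)
#' @rdname accessors
setMethod("meanSimilarity", "SimilarityField", function(object) object@w)
#' @rdname accessors
setMethod("controlValues", "ControlField", function(object) object@delta)

setMethod("show", "SystemModel", function(object) {
  cat("SystemModel:", object@nBins, "bins x", object@nAngles,
      "views over 180 deg,", object@imageSize, "x", object@imageSize,
      "image grid\n")
  cat("  nonzero weights:", length(object@H@x), "\n")
})

setMethod("show", "SubsetPartition", function(object) {
  cat("SubsetPartition:", object@nSubsets, "subsets of",
      object@nAngles, "views (interleaved)\n")
})

setMethod("show", "PenaltySpec", function(object) {
  if (object@kind == "QD") cat("PenaltySpec: QD (quadratic)\n")
  else cat("PenaltySpec:", object@kind, "with control =", object@control, "\n")
})

setMethod("show", "SimilarityField", function(object) {
  cat("SimilarityField:", paste(dim(object@W)[1:2], collapse = " x "),
      "grid, patch radius", object@patchRadius, "\n")
  cat("  mean pair weight w =", format(object@w, digits = 4),
      ", bandwidth h =", format(object@h, digits = 4), "\n")
})

setMethod("show", "ControlField", function(object) {
  dv <- object@delta[!is.na(object@delta)]
  cat("ControlField: delta0 =", object@delta0,
      ", fine-tuned range [", format(min(dv), digits = 4), ",",
      format(max(dv), digits = 4), "]\n")
})

setMethod("show", "ROISet", function(object) {
  cat("ROISet on a", object@imageSize, "x", object@imageSize, "grid:",
      length(object@regional), "regional,", length(object@crc),
      "contrast-recovery ROIs + background\n")
})

setMethod("show", "ReconResult", function(object) {
  cat("ReconResult:", object@method, "estimate",
      paste(dim(object@estimate), collapse = " x "), "\n")
  if (length(object@history))
    cat("  final objective:",
        format(object@history[length(object@history)], digits = 8), "after",
        length(object@history), "outer iterations\n")
})
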