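#' Extract the pixel matrix
#' @param x an object carrying pixels (e.g. \linkS4class{GrayImage}).
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Declared intensity bounds of an image
#' @param x a \linkS4class{GrayImage}.
#' @return numeric length-2 (min, max).
#' @export
setGeneric("valueRange", function(x) standardGeneric("valueRange"))

#' Extract a binary mask matrix
#' @param x an \linkS4class{EdgeMap} or \linkS4class{RoiMask}.
#' @return logical matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Is a region-of-interest mask empty?
#' @param x a \linkS4class{RoiMask}.
#' @return logical scalar.
#' @export
setGeneric("isEmptyRoi", function(x) standardGeneric("isEmptyRoi"))

#' Normalized co-occurrence probabilities
#' @param x a \linkS4class{CooccurrenceMatrix}.
#' @return numeric matrix summing to 1.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' Raw co-occurrence pair counts
#' @param x a \linkS4class{CooccurrenceMatrix}.
#' @return numeric matrix of counts.
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' Included-feature indicator of a selection result
#' @param x a \linkS4class{SelectionMask}.
#' @return named logical vector.
#' @export
setGeneric("includedFeatures", function(x) standardGeneric("includedFeatures"))

#' Per-class one-vs-rest confusion tallies
#' @param x a \linkS4class{ConfusionCounts}.
#' @return data.frame with columns class, TP, TN, FP, FN.
#' @export
setGeneric("perClassCounts", function(x) standardGeneric("perClassCounts"))

#' Area under a ROC curve
#' @param x a \linkS4class{RocCurve}.
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' Evaluation report of a pipeline run
#' @param x a \linkS4class{PipelineRun}.
#' @return list.
#' @export
setGeneric("runReport", function(x) standardGeneric("runReport"))

#' Provenance (configs and seeds) of a pipeline run
#' @param x a \linkS4class{PipelineRun}.
#' @return list.
#' @export
setGeneric("runProvenance", function(x) standardGeneric("runProvenance"))
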