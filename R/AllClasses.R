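#' @import methods
NULL

#' GrayImage: a 2-D grayscale intensity image
#'
#' The universal pixel carrier of the pipeline: a numeric matrix of
#' intensities together with its declared value range (by default the 8-bit
#' range \code{c(0, 255)}).  Validity requires all pixels to be finite,
#' within the declared range, and the image to be at least 3 x 3.
#'
#' @slot pixels numeric matrix of intensities (rows = image rows).
#' @slot range numeric length-2, declared (min, max) intensity bounds.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", range = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 3L || ncol(p) < 3L) return("image must be at least 3 x 3")
    if (length(object@range) != 2L || any(!is.finite(object@range)))
      return("range must be two finite numbers")
    if (object@range[1] >= object@range[2])
      return("range must be increasing")
    if (any(!is.finite(p))) return("pixels must be finite")
    tol <- 1e-9
    if (min(p) < object@range[1] - tol || max(p) > object@range[2] + tol)
      return("pixels outside declared value range")
    TRUE
  }
)

#' GradientField: signed gradient responses and derived direction
#'
#' Holds the x/y kernel responses, the gradient magnitude
#' \eqn{|P| = \sqrt{P_x^2 + P_y^2}}, and the edge direction
#' \eqn{\alpha = \arctan(|P_x| / |P_y|)} in degrees (90 at \eqn{|P_y| = 0}).
#'
#' @slot px,py numeric matrices of signed x/y responses.
#' @slot magnitude numeric matrix, elementwise \code{sqrt(px^2 + py^2)}.
#' @slot alpha numeric matrix of directions in [0, 90] degrees.
#' @export
setClass("GradientField",
  representation(px = "matrix", py = "matrix",
                 magnitude = "matrix", alpha = "matrix"),
  validity = function(object) {
    d <- dim(object@px)
    if (!identical(d, dim(object@py)) || !identical(d, dim(object@magnitude)) ||
        !identical(d, dim(object@alpha)))
      return("px, py, magnitude, alpha must share dimensions")
    if (max(abs(object@magnitude -
                sqrt(object@px^2 + object@py^2))) > 1e-8)
      return("magnitude must equal sqrt(px^2 + py^2)")
    a <- object@alpha
    if (min(a) < -1e-9 || max(a) > 90 + 1e-9)
      return("alpha must lie in [0, 90] degrees")
    TRUE
  }
)

#' EdgeMap: binary edge-pixel map with provenance
#'
#' @slot edges logical matrix marking edge pixels.
#' @slot provenance list of the configuration (and seed) that produced it.
#' @export
setClass("EdgeMap",
  representation(edges = "matrix", provenance = "list"),
  validity = function(object) {
    if (!is.logical(object@edges)) return("edges must be a logical matrix")
    TRUE
  }
)

#' RoiMask: binary region-of-interest mask
#'
#' An all-\code{FALSE} mask is the documented "empty ROI" signal emitted when
#' the edge map encloses no region; it is not an error.
#'
#' @slot mask logical matrix marking ROI pixels.
#' @export
setClass("RoiMask",
  representation(mask = "matrix"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    TRUE
  }
)

#' CooccurrenceMatrix: SGLDM joint gray-level pair distribution
#'
#' Counts and normalized probabilities of gray-level pairs at displacement
#' (distance \code{v}, angle \code{mu}); the second-order joint conditional
#' density the texture features are computed from.
#'
#' @slot counts Xg x Xg matrix of nonnegative pair counts.
#' @slot probabilities counts normalized to sum 1.
#' @slot v integer inter-sample distance.
#' @slot mu angle in degrees, one of 0, 45, 90, 135.
#' @slot symmetric logical, whether reversed pairs were also counted.
#' @export
setClass("CooccurrenceMatrix",
  representation(counts = "matrix", probabilities = "matrix",
                 v = "integer", mu = "integer", symmetric = "logical"),
  validity = function(object) {
    if (!identical(dim(object@counts), dim(object@probabilities)))
      return("counts and probabilities must share dimensions")
    if (nrow(object@counts) != ncol(object@counts))
      return("co-occurrence matrix must be square")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    if (sum(object@counts) > 0 &&
        abs(sum(object@probabilities) - 1) > 1e-12)
      return("probabilities must sum to 1")
    if (!(object@mu %in% c(0L, 45L, 90L, 135L)))
      return("mu must be one of 0, 45, 90, 135")
    if (object@symmetric &&
        max(abs(object@counts - t(object@counts))) > 0)
      return("symmetric flag set but counts not symmetric")
    TRUE
  }
)

#' LabeledImageSet: images with class labels and ground-truth masks
#'
#' @slot images list of \linkS4class{GrayImage}.
#' @slot labels integer class labels in \{1, 2, 3\}.
#' @slot masks list (one per image) of logical skull/brain/tumor masks.
#' @export
setClass("LabeledImageSet",
  representation(images = "list", labels = "integer", masks = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n || length(object@masks) != n)
      return("images, labels and masks must have equal length")
    if (n > 0 && !all(object@labels %in% 1:3))
      return("labels must be in 1..3")
    TRUE
  }
)

#' SelectionMask: result of wrapper feature selection
#'
#' @slot included named logical, one entry per feature; never all-FALSE.
#' @slot fitness achieved wrapper objective (lower is better).
#' @slot provenance list holding configuration and seed.
#' @export
setClass("SelectionMask",
  representation(included = "logical", fitness = "numeric",
                 provenance = "list"),
  validity = function(object) {
    if (!any(object@included)) return("at least one feature must be included")
    TRUE
  }
)

#' ResidualNetwork: a depth-configurable residual network
#'
#' Either an image-mode convolutional network (stem, bottleneck stages,
#' global average pooling, softmax head) or a feature-mode network of
#' residual fully-connected blocks over a selected-feature vector.
#'
#' @slot mode "image" or "feature".
#' @slot config the \code{networkConfig()} list used to build it.
#' @slot layers list of layer parameter objects.
#' @slot trained logical.
#' @export
setClass("ResidualNetwork",
  representation(mode = "character", config = "list", layers = "list",
                 trained = "logical"),
  validity = function(object) {
    if (!(object@mode %in% c("image", "feature")))
      return("mode must be 'image' or 'feature'")
    TRUE
  }
)

#' ConfusionCounts: multiclass confusion matrix
#'
#' Predicted classes along rows, actual classes along columns; per-class
#' one-vs-rest TP/TN/FP/FN tallies derive from the matrix.
#'
#' @slot table m x m integer matrix (rows = predicted, columns = actual).
#' @slot class_labels the class labels, in matrix order.
#' @export
setClass("ConfusionCounts",
  representation(table = "matrix", class_labels = "character"),
  validity = function(object) {
    if (nrow(object@table) != ncol(object@table))
      return("confusion matrix must be square")
    if (length(object@class_labels) != nrow(object@table))
      return("class_labels length must match matrix dimension")
    if (any(object@table < 0)) return("counts must be nonnegative")
    TRUE
  }
)

#' RocCurve: one-vs-rest receiver operating characteristic
#'
#' @slot thresholds decision thresholds, decreasing.
#' @slot tpr,fpr true/false positive rates along the curve.
#' @slot auc trapezoidal area under the curve.
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric"),
  validity = function(object) {
    if (length(object@tpr) != length(object@fpr))
      return("tpr and fpr must have equal length")
    if (any(object@tpr < -1e-12) || any(object@tpr > 1 + 1e-12) ||
        any(object@fpr < -1e-12) || any(object@fpr > 1 + 1e-12))
      return("rates must lie in [0, 1]")
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
      return("auc must lie in [0, 1]")
    TRUE
  }
)

#' PipelineRun: record of one end-to-end pipeline execution
#'
#' @slot report list with the evaluation report (confusion matrix, metrics,
#'   ROC areas) and per-stage summaries.
#' @slot provenance list capturing every effective configuration and seed.
#' @export
setClass("PipelineRun",
  representation(report = "list", provenance = "list"))
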