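#' Multiclass confusion matrix
#'
#' Builds the m x m confusion matrix with predicted classes along the rows
#' and actual classes along the columns, plus the per-class one-vs-rest
#' TP/TN/FP/FN reductions.
#'
#' @param predicted,truth equal-length label vectors.
#' @param class_labels the full label set; defaults to the sorted union.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(predicted, truth, class_labels = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (is.null(class_labels))
    class_labels <- sort(unique(c(predicted, truth)))
  class_labels <- as.character(class_labels)
  p <- as.character(predicted); a <- as.character(truth)
  if (!all(p %in% class_labels) || !all(a %in% class_labels))
    stop("unknown label outside class_labels")
  m <- length(class_labels)
  tab <- matrix(0L, m, m, dimnames = list(predicted = class_labels,
                                          actual = class_labels))
  for (i in seq_along(p))
    tab[p[i], a[i]] <- tab[p[i], a[i]] + 1L
  new("ConfusionCounts", table = tab, class_labels = class_labels)
}

#' @rdname perClassCounts
#' @export
setMethod("perClassCounts", "ConfusionCounts", function(x) {
  tab <- x@table
  total <- sum(tab)
  out <- lapply(seq_along(x@class_labels), function(k) {
    tp <- tab[k, k]
    fp <- sum(tab[k, ]) - tp   # predicted k, actually other
    fn <- sum(tab[, k]) - tp   # actually k, predicted other
    tn <- total - tp - fp - fn
    data.frame(class = x@class_labels[k], TP = tp, TN = tn, FP = fp,
               FN = fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (rows = predicted, columns = actual):\n")
  print(object@table)
})

#' Accuracy, precision and recall from confusion counts
#'
#' Per class (one-vs-rest): accuracy = (TP + TN) / (TP + TN + FP + FN),
#' precision = TP / (TP + FP), recall = TP / (TP + FN) — the standard
#' definitions, exactly.  A zero denominator yields a defined 0 with a
#' warning.  Macro averages plus the micro accuracy (matrix trace over
#' total) are included.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return list with \code{per_class} (data.frame), \code{macro} (named
#'   vector) and \code{micro_accuracy}.
#' @export
summaryMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  pc <- perClassCounts(counts)
  if (sum(counts@table) == 0L) stop("empty counts")
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning(sprintf("%s: zero denominator, reported as 0", what))
    out
  }
  pc$accuracy <- safe_div(pc$TP + pc$TN, pc$TP + pc$TN + pc$FP + pc$FN,
                          "accuracy")
  pc$precision <- safe_div(pc$TP, pc$TP + pc$FP, "precision")
  pc$recall <- safe_div(pc$TP, pc$TP + pc$FN, "recall")
  list(per_class = pc,
       macro = c(accuracy = mean(pc$accuracy),
                 precision = mean(pc$precision),
                 recall = mean(pc$recall)),
       micro_accuracy = sum(diag(counts@table)) / sum(counts@table))
}

#' One-vs-rest ROC curve with trapezoidal AUC
#'
#' Thresholds over all distinct scores (plus the trivial endpoints); TPR
#' and FPR are monotone along the curve and the area is the trapezoidal
#' sum.  Perfectly separating scores give area 1; scores independent of the
#' labels (e.g. all equal) give 0.5.
#'
#' @param scores numeric scores in [0, 1] (probability of the positive
#'   class).
#' @param truth label vector.
#' @param positive_class the class treated as positive.
#' @return a \linkS4class{RocCurve}.
#' @export
rocCurve <- function(scores, truth, positive_class) {
  if (length(scores) != length(truth)) stop("length mismatch")
  if (any(scores < -1e-9 | scores > 1 + 1e-9))
    stop("scores must lie in [0, 1]")
  pos <- truth == positive_class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("undefined curve: truth contains a single class")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = th, tpr = tpr, fpr = fpr, auc = auc)
}

#' @rdname aucValue
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve with %d thresholds, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})
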