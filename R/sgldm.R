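#' SGLDM configuration
#'
#' @param gray_levels number of quantization levels Xg (>= 2); default 32
#'   balances matrix sparsity against discrimination on 8-bit input.
#' @param distances inter-sample distances v (each >= 1).
#' @param angles_deg subset of \code{c(0, 45, 90, 135)}.
#' @param symmetric count reversed pairs too (standard GLCM practice).
#' @return list of class \code{"SgldmConfig"}.
#' @export
sgldmConfig <- function(gray_levels = 32L, distances = c(1L, 2L),
                        angles_deg = c(0L, 45L, 90L, 135L),
                        symmetric = TRUE) {
  gray_levels <- as.integer(gray_levels)
  if (gray_levels < 2L) stop("gray_levels must be >= 2")
  if (any(distances < 1)) stop("distances must be >= 1")
  if (!all(angles_deg %in% c(0, 45, 90, 135)))
    stop("angles must be drawn from 0, 45, 90, 135")
  structure(list(gray_levels = gray_levels,
                 distances = as.integer(distances),
                 angles_deg = as.integer(angles_deg),
                 symmetric = isTRUE(symmetric)),
            class = "SgldmConfig")
}

#' Quantize an image to Xg gray levels
#'
#' Level = \code{floor(pixel * Xg / (range_max + 1))}, clipped to
#' \code{[0, Xg - 1]}; a pixel at the brightest value maps to level Xg - 1.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param Xg number of levels (>= 2).
#' @return integer matrix of levels with attribute \code{"Xg"}.
#' @export
quantizeImage <- function(image, Xg) {
  stopifnot(is(image, "GrayImage"))
  Xg <- as.integer(Xg)
  if (Xg < 2L) stop("Xg must be >= 2")
  rmax <- valueRange(image)[2]
  q <- floor(pixels(image) * Xg / (rmax + 1))
  q <- matrix(as.integer(clamp(q, 0, Xg - 1L)), nrow(q), ncol(q))
  attr(q, "Xg") <- Xg
  q
}

# displacement (row, col) for angle mu and distance v
sgldm_offset <- function(v, mu) {
  switch(as.character(mu),
         "0" = c(0L, v), "45" = c(-v, v), "90" = c(-v, 0L),
         "135" = c(-v, -v),
         stop("mu must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence (SGLDM) matrix
#'
#' Counts gray-level pairs (p, p + offset) for displacement (distance
#' \code{v}, angle \code{mu}) where both pixels lie inside the ROI (the whole
#' image when \code{roi} is NULL); symmetric counting adds the reversed
#' pair.  Probabilities are counts normalized by their total.
#'
#' @param quantized integer level matrix from \code{\link{quantizeImage}}.
#' @param roi optional \linkS4class{RoiMask} or logical matrix.
#' @param v distance (>= 1).
#' @param mu angle in degrees, one of 0, 45, 90, 135.
#' @param symmetric logical.
#' @param Xg level count; taken from the quantized matrix when absent.
#' @return a \linkS4class{CooccurrenceMatrix}.
#' @export
cooccurrence <- function(quantized, roi = NULL, v = 1L, mu = 0L,
                         symmetric = TRUE, Xg = attr(quantized, "Xg")) {
  if (is.null(Xg)) stop("Xg not given and not carried by quantized matrix")
  v <- as.integer(v); mu <- as.integer(mu); Xg <- as.integer(Xg)
  if (v < 1L) stop("v must be >= 1")
  off <- sgldm_offset(v, mu)
  nr <- nrow(quantized); nc <- ncol(quantized)
  if (is(roi, "RoiMask")) roi <- maskMatrix(roi)
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  ok_r <- rs + off[1] >= 1L & rs + off[1] <= nr
  ok_c <- cs + off[2] >= 1L & cs + off[2] <= nc
  r1 <- rs[ok_r]; c1 <- cs[ok_c]
  if (length(r1) == 0L || length(c1) == 0L)
    stop("degenerate input: no pixel pairs admit the requested offset")
  src_ok <- roi[r1, c1, drop = FALSE]
  dst_ok <- roi[r1 + off[1], c1 + off[2], drop = FALSE]
  use <- src_ok & dst_ok
  i <- quantized[r1, c1, drop = FALSE][use]
  j <- quantized[r1 + off[1], c1 + off[2], drop = FALSE][use]
  if (length(i) == 0L)
    stop("degenerate input: ROI has fewer than 2 pixels admitting the offset")
  counts <- matrix(tabulate(i * Xg + j + 1L, Xg * Xg), Xg, Xg, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  new("CooccurrenceMatrix", counts = counts,
      probabilities = counts / sum(counts),
      v = v, mu = mu, symmetric = isTRUE(symmetric))
}

#' @rdname probabilities
#' @export
setMethod("probabilities", "CooccurrenceMatrix", function(x) x@probabilities)

#' @rdname pairCounts
#' @export
setMethod("pairCounts", "CooccurrenceMatrix", function(x) x@counts)

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix %d x %d (v = %d, mu = %d%s), %g pairs\n",
              nrow(object@counts), ncol(object@counts), object@v, object@mu,
              if (object@symmetric) ", symmetric" else "",
              sum(object@counts)))
})

#' Haralick-family texture features of a co-occurrence matrix
#'
#' Standard second-order texture descriptors of the normalized matrix
#' \eqn{p(i,j)} (levels indexed from 0):
#' energy \eqn{\sum p^2}; contrast \eqn{\sum (i-j)^2 p};
#' entropy \eqn{-\sum p \ln p} (natural log, \eqn{0\ln 0 = 0});
#' homogeneity \eqn{\sum p / (1 + (i-j)^2)};
#' correlation \eqn{\sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)}
#' (defined as 1 when a marginal variance is zero);
#' variance \eqn{\sum (i-\mu_i)^2 p}; maximum probability \eqn{\max p};
#' dissimilarity \eqn{\sum |i-j| p}.
#'
#' @param cm a \linkS4class{CooccurrenceMatrix} (or normalized matrix).
#' @return named numeric vector of the 8 features.
#' @export
textureFeatures <- function(cm) {
  p <- if (is(cm, "CooccurrenceMatrix")) probabilities(cm) else cm
  n <- nrow(p)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  corr <- if (var_i <= 1e-15 || var_j <= 1e-15) {
    message("textureFeatures: zero marginal variance, correlation set to 1")
    1
  } else sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  plog <- ifelse(p > 0, p * log(p), 0)
  c(energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    entropy = -sum(plog),
    homogeneity = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    variance = var_i,
    maximum_probability = max(p),
    dissimilarity = sum(abs(i - j) * p))
}

#' Extract the SGLDM feature vector of a region of interest
#'
#' Quantizes the image, builds one co-occurrence matrix per (distance,
#' angle) pair of the configuration, computes the 8 texture features of
#' each, and concatenates them in a stable documented order: distances
#' outermost, then angles, then features, named
#' \code{"v<dist>.a<angle>.<feature>"}.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param roi a \linkS4class{RoiMask} or logical matrix (NULL = whole image).
#' @param config an \code{\link{sgldmConfig}}.
#' @return named numeric feature vector of length
#'   \code{8 * length(distances) * length(angles)}.
#' @export
extractRoiFeatures <- function(image, roi = NULL, config = sgldmConfig()) {
  stopifnot(is(image, "GrayImage"), inherits(config, "SgldmConfig"))
  if (is(roi, "RoiMask")) {
    if (isEmptyRoi(roi)) stop("ROI is empty")
    roi <- maskMatrix(roi)
  }
  q <- quantizeImage(image, config$gray_levels)
  out <- numeric(0)
  for (v in config$distances) {
    for (mu in config$angles_deg) {
      cm <- cooccurrence(q, roi = roi, v = v, mu = mu,
                         symmetric = config$symmetric)
      f <- textureFeatures(cm)
      names(f) <- sprintf("v%d.a%d.%s", v, mu, names(f))
      out <- c(out, f)
    }
  }
  out
}

#' SGLDM feature table for a labeled image set
#'
#' Convenience wrapper: per-image ROI masks (or NULL for whole images) are
#' paired with the images and the per-image feature vectors stacked into a
#' matrix with a final \code{label} attribute.
#'
#' @param images list of \linkS4class{GrayImage}.
#' @param rois list of masks (or NULL entries), recycled if NULL.
#' @param config an \code{\link{sgldmConfig}}.
#' @return matrix, one row per image, feature names as columns.
#' @export
featureTable <- function(images, rois = NULL, config = sgldmConfig()) {
  rows <- lapply(seq_along(images), function(i) {
    roi <- if (is.null(rois)) NULL else rois[[i]]
    extractRoiFeatures(images[[i]], roi, config)
  })
  do.call(rbind, rows)
}
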