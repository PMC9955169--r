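#' Median filtering
#'
#' Replaces each pixel by the median of its square window neighborhood
#' (edge-replication padding).  The workhorse denoiser for salt-and-pepper
#' corrupted slices; idempotent on constant images and never widens the
#' intensity range.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param window odd window side length, >= 3.
#' @return filtered \linkS4class{GrayImage}.
#' @export
medianFilter <- function(image, window = 3L) {
  stopifnot(is(image, "GrayImage"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  GrayImage(median_filter_rcpp(pixels(image), window),
            range = valueRange(image))
}

#' Estimate the salt-and-pepper corruption fraction
#'
#' Counts extreme-valued pixels (at the declared range bounds) that are
#' isolated, i.e. whose 3x3 neighborhood median differs from them by more
#' than a quarter of the intensity range.  Drives the automatic
#' denoise-or-not decision of the pipeline.
#'
#' @param image a \linkS4class{GrayImage}.
#' @return estimated corrupted-pixel fraction in [0, 1].
#' @export
estimateSaltPepper <- function(image) {
  p <- pixels(image)
  r <- valueRange(image)
  med <- median_filter_rcpp(p, 3L)
  extreme <- (p <= r[1] + 1e-9) | (p >= r[2] - 1e-9)
  isolated <- abs(p - med) > 0.25 * diff(r)
  mean(extreme & isolated)
}

#' Morphology configuration for skull stripping
#'
#' @param radius disk structuring-element radius in pixels (>= 1).
#' @param binarize_threshold numeric intensity cut, or \code{"otsu"}.
#' @return list of class \code{"MorphConfig"}.
#' @export
morphConfig <- function(radius = NULL, binarize_threshold = "otsu") {
  if (!is.null(radius) && radius < 1) stop("radius must be >= 1")
  structure(list(radius = radius,
                 binarize_threshold = binarize_threshold),
            class = "MorphConfig")
}

#' Strip the skull ring from a brain slice
#'
#' Binarizes the image (Otsu by default), erodes with a disk to disconnect
#' the thin bright skull ring from the brain, keeps the largest connected
#' component, and dilates with the same disk to restore the brain's extent.
#' The stated erosion/dilation account of skull removal is terse in the
#' method this follows; the erode / largest-component / dilate sequence here
#' is a standard reconstruction of it.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param config a \code{\link{morphConfig}}; the default disk radius is
#'   \code{max(3, image_size / 32)} so it scales with the image.
#' @return list with \code{image} (skull-free \linkS4class{GrayImage},
#'   non-brain pixels zeroed) and \code{mask} (logical brain mask).
#' @export
stripSkull <- function(image, config = morphConfig()) {
  stopifnot(is(image, "GrayImage"))
  p <- pixels(image)
  thr <- config$binarize_threshold
  if (identical(thr, "otsu")) thr <- otsu_threshold(p, valueRange(image))
  bin <- p > thr
  if (!any(bin)) stop("degenerate input: empty foreground after binarization")
  r <- config$radius
  if (is.null(r)) r <- max(3L, round(min(dim(p)) / 32))
  se <- disk_se(r)
  eroded <- morph_rcpp(bin, se, TRUE)
  if (!any(eroded)) {
    # erosion removed everything; fall back to the raw foreground
    eroded <- bin
  }
  core <- largest_component(eroded)
  mask <- morph_rcpp(core, se, FALSE)
  mask <- mask & bin  # dilation must not resurrect background
  mask <- largest_component(mask)
  out <- p
  out[!mask] <- 0
  list(image = GrayImage(out, range = valueRange(image)), mask = mask)
}

#' Rotation matrix
#'
#' The 2-D rotation operator
#' \deqn{\tau(\theta) = \begin{pmatrix} \cos\theta & -\sin\theta \\
#'   \sin\theta & \cos\theta \end{pmatrix}}
#' used by the augmentation stage; orthogonal with determinant 1.
#'
#' @param theta_deg rotation angle in degrees.
#' @return 2 x 2 numeric matrix.
#' @export
rotationMatrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Augmentation plan
#'
#' @param angles_deg rotation angles in degrees, each in (-180, 180].
#' @param flips subset of \code{c("horizontal", "vertical")}.
#' @param interpolation \code{"bilinear"} (default) or \code{"nearest"}.
#' @return list of class \code{"AugmentationPlan"}.
#' @export
augmentationPlan <- function(angles_deg = c(-15, 15, -90, 90),
                             flips = "horizontal",
                             interpolation = c("bilinear", "nearest")) {
  if (any(angles_deg <= -180 | angles_deg > 180))
    stop("angles must lie in (-180, 180]")
  flips <- match.arg(flips, c("horizontal", "vertical"),
                     several.ok = TRUE)
  structure(list(angles_deg = angles_deg, flips = unique(flips),
                 interpolation = match.arg(interpolation)),
            class = "AugmentationPlan")
}

# Rotate clockwise by theta about the center pixel, preserving dimensions;
# pixels mapped from outside the frame are filled with 0.
rotate_image <- function(p, theta_deg, interpolation = "bilinear") {
  nr <- nrow(p); nc <- ncol(p)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- theta_deg * pi / 180
  rows <- matrix(seq_len(nr) - cr, nr, nc)
  cols <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)
  # inverse mapping: source = tau(-theta) applied to destination offsets
  sr <- cos(th) * rows - sin(th) * cols + cr
  sc <- sin(th) * rows + cos(th) * cols + cc
  out <- matrix(0, nr, nc)
  if (interpolation == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- p[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
    g <- function(ri, ci) p[cbind(ri[ok], ci[ok])]
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * g(r0, c0) +
               (1 - fr[ok]) * fc[ok]       * g(r0, c0 + 1) +
               fr[ok]       * (1 - fc[ok]) * g(r0 + 1, c0) +
               fr[ok]       * fc[ok]       * g(r0 + 1, c0 + 1)
  }
  out
}

flip_image <- function(p, axis) {
  switch(axis,
         horizontal = p[, rev(seq_len(ncol(p))), drop = FALSE],
         vertical = p[rev(seq_len(nrow(p))), , drop = FALSE],
         stop("unknown flip axis"))
}

#' Rotation/flip data augmentation
#'
#' Produces one output per (angle x flip) combination — the "no flip" case
#' counts as a flip option — so the output count is
#' \code{length(angles) * (length(flips) + 1)}, plus the original image when
#' \code{include_original}.  Rotation is clockwise about the center pixel
#' with the plan's interpolation; out-of-frame pixels are filled with 0.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param plan an \code{\link{augmentationPlan}}.
#' @param include_original prepend the unmodified image?
#' @return list of \linkS4class{GrayImage}.
#' @export
augmentImage <- function(image, plan = augmentationPlan(),
                         include_original = FALSE) {
  stopifnot(is(image, "GrayImage"), inherits(plan, "AugmentationPlan"))
  p <- pixels(image)
  rng <- valueRange(image)
  out <- list()
  if (include_original) out[[length(out) + 1L]] <- image
  for (ang in plan$angles_deg) {
    rotated <- if (ang == 0) p else rotate_image(p, ang, plan$interpolation)
    for (fl in c("none", plan$flips)) {
      q <- if (fl == "none") rotated else flip_image(rotated, fl)
      out[[length(out) + 1L]] <- GrayImage(clamp(q, rng[1], rng[2]),
                                           range = rng)
    }
  }
  out
}

#' Decide whether to denoise, then do it
#'
#' The denoising step is optional; when \code{denoise = "auto"} the filter is
#' applied only if the estimated salt-and-pepper fraction exceeds 0.5\%
#' (\code{\link{estimateSaltPepper}}).  The decision is recorded in the
#' result.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param denoise TRUE, FALSE or \code{"auto"}.
#' @param window median window.
#' @return list with \code{image} and logical \code{applied}.
#' @export
maybeDenoise <- function(image, denoise = "auto", window = 3L) {
  apply_it <- if (identical(denoise, "auto"))
    estimateSaltPepper(image) > 0.005 else isTRUE(denoise)
  list(image = if (apply_it) medianFilter(image, window) else image,
       applied = apply_it)
}
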