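#' Canny configuration
#'
#' @param beta center weight of the 3x3 smoothing kernel
#'   \eqn{K = [1,1,1; 1,\beta,1; 1,1,1]}; the default is 2.
#' @param log_sigma Gaussian scale of the Laplacian-of-Gaussian stage.
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, \code{0 < low < high <= 1}.
#' @return list of class \code{"CannyConfig"}.
#' @export
cannyConfig <- function(beta = 2, log_sigma = 1, low_frac = 0.1,
                        high_frac = 0.2) {
  if (beta <= 0) stop("beta must be > 0")
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1))
    stop("need 0 < low_frac < high_frac <= 1")
  structure(list(beta = beta, log_sigma = log_sigma,
                 low_frac = low_frac, high_frac = high_frac),
            class = "CannyConfig")
}

#' Mayfly swarm configuration
#'
#' @param swarm_size number of mayflies (>= 2).
#' @param iterations search iterations.
#' @param d_bounds interval for the distance coefficients d1, d2; \code{NULL}
#'   defaults to \code{[0, 0.25 * max |P|]} of the field being adjusted
#'   (perturbations beyond the gradient scale destroy the field).
#' @param seed integer seed.
#' @return list of class \code{"MayflyConfig"}.
#' @export
mayflyConfig <- function(swarm_size = 15L, iterations = 20L,
                         d_bounds = NULL, seed = 1L) {
  if (swarm_size < 2L) stop("swarm_size must be >= 2")
  if (!is.null(d_bounds) && any(!is.finite(d_bounds)))
    stop("d_bounds must be finite")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 d_bounds = d_bounds, seed = as.integer(seed)),
            class = "MayflyConfig")
}

#' Laplacian-of-Gaussian prefilter with image-of-interest retention
#'
#' Computes the LoG response at scale \code{sigma} and keeps the pixels
#' whose intensity is at least the response (the "image of interest"),
#' zeroing the rest.  On a constant image the LoG response is zero
#' everywhere, so every pixel is retained.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param sigma Gaussian scale, > 0.
#' @return filtered \linkS4class{GrayImage}.
#' @export
logFilter <- function(image, sigma = 1) {
  stopifnot(is(image, "GrayImage"))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  p <- pixels(image)
  k <- log_kernel(sigma)
  resp <- conv2_rcpp(p, k, 1L)
  out <- ifelse(p >= resp, p, 0)
  GrayImage(out, range = valueRange(image))
}

# Discrete LoG kernel, zero-sum, size 2*ceil(3 sigma) + 1.
log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  idx <- -h:h
  g <- outer(idx, idx, function(i, j)
    (i^2 + j^2 - 2 * sigma^2) / sigma^4 *
      exp(-(i^2 + j^2) / (2 * sigma^2)))
  g - mean(g)
}

#' Weighted-center kernel smoothing
#'
#' Convolves with \eqn{K = [1,1,1; 1,\beta,1; 1,1,1]} normalized by its
#' weight sum \eqn{8 + \beta}, with edge-replication padding, so constant
#' images are preserved exactly.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param config a \code{\link{cannyConfig}} (only \code{beta} is used).
#' @return smoothed \linkS4class{GrayImage}.
#' @export
smoothImage <- function(image, config = cannyConfig()) {
  stopifnot(is(image, "GrayImage"))
  k <- matrix(1, 3, 3)
  k[2, 2] <- config$beta
  k <- k / (8 + config$beta)
  GrayImage(conv2_rcpp(pixels(image), k, 1L), range = valueRange(image))
}

#' Sobel-form gradient field
#'
#' Applies the x/y 3x3 gradient kernels (Sobel form), computes the magnitude
#' \eqn{|P| = \sqrt{P_x^2 + P_y^2}} and the direction
#' \eqn{\alpha = \arctan(|P_x|/|P_y|)} in degrees, with the \eqn{|P_y| = 0}
#' limit mapped to 90.  The x kernel responds to horizontal intensity change
#' (vertical edges).
#'
#' @param image a \linkS4class{GrayImage} (at least 3x3).
#' @param squared if TRUE, store the squared magnitude as printed in some
#'   accounts (audit flag); the default applies the square root, the
#'   universal convention.
#' @return a \linkS4class{GradientField}.
#' @export
computeGradients <- function(image, squared = FALSE) {
  stopifnot(is(image, "GrayImage"))
  p <- pixels(image)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # columns -1,0,1
  ky <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)
  px <- conv2_rcpp(p, kx, 1L)
  py <- conv2_rcpp(p, ky, 1L)
  gradient_field(px, py, squared = squared)
}

gradient_field <- function(px, py, squared = FALSE) {
  mag <- sqrt(px^2 + py^2)
  alpha <- atan2(abs(px), abs(py)) * 180 / pi  # 90 when |py| = 0
  f <- new("GradientField", px = px, py = py, magnitude = mag,
           alpha = alpha)
  if (squared) attr(f, "squared_magnitude") <- mag^2
  f
}

# ---- non-maximum suppression and hysteresis ---------------------------------

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Thin the magnitude ridge: keep pixels not smaller than the magnitude
# interpolated at unit distance along the gradient direction on either side
# (sub-pixel non-maximum suppression; exact plateau ties at diagonal
# quantization otherwise leave 2-wide corners).
non_max_suppress <- function(px, py, mag) {
  apx <- abs(px); apy <- abs(py)
  sc <- ifelse(px >= 0, 1L, -1L)
  sr <- ifelse(py >= 0, 1L, -1L)
  horiz <- apx >= apy
  t <- ifelse(horiz, apy / pmax(apx, 1e-300), apx / pmax(apy, 1e-300))
  S <- function(dr, dc) shift_mat(mag, dr, dc)
  m1 <- matrix(0, nrow(mag), ncol(mag)); m2 <- m1
  for (srv in c(-1L, 1L)) {
    for (scv in c(-1L, 1L)) {
      selA <- horiz & sr == srv & sc == scv
      if (any(selA)) {
        a <- (1 - t) * S(0, scv) + t * S(srv, scv)
        b <- (1 - t) * S(0, -scv) + t * S(-srv, -scv)
        m1[selA] <- a[selA]; m2[selA] <- b[selA]
      }
      selB <- !horiz & sr == srv & sc == scv
      if (any(selB)) {
        a <- (1 - t) * S(srv, 0) + t * S(srv, scv)
        b <- (1 - t) * S(-srv, 0) + t * S(-srv, -scv)
        m1[selB] <- a[selB]; m2[selB] <- b[selB]
      }
    }
  }
  keep <- mag > 0 & mag >= m1 & mag >= m2
  out <- mag
  out[!keep] <- 0
  out
}

hysteresis <- function(nms_mag, max_mag, low_frac, high_frac) {
  # magnitudes at floating-point noise level count as zero (constant images)
  if (max_mag <= 1e-6) return(nms_mag > Inf)
  lo <- low_frac * max_mag
  hi <- high_frac * max_mag
  weak <- nms_mag >= lo
  strong <- nms_mag >= hi
  if (!any(strong)) return(strong)
  lab <- label_components_rcpp(weak, 8L)
  keep <- matrix(lab %in% unique(lab[strong]), nrow(lab), ncol(lab))
  weak & keep
}

#' Mayfly adjustment of a gradient field
#'
#' Searches the distance-coefficient plane (d1, d2) with a small swarm: each
#' mayfly holds a (d1, d2) position, draws fresh random coefficients
#' a1, a2 in [-1, 1] every iteration, perturbs the gradient arrays globally
#' (\eqn{P_x = P_{xi} + d_1 a_1}, \eqn{P_y = P_{yi} + d_2 a_2}), re-derives
#' the direction from the adjusted components, and scores the resulting edge
#' map with the fitness functional.  Global-best elitism makes the
#' best-so-far fitness non-decreasing.
#'
#' @param field a \linkS4class{GradientField}.
#' @param config a \code{\link{mayflyConfig}}.
#' @param fitness function(edge_map, field) returning a scalar to maximize;
#'   default \code{\link{edgeContinuityFitness}}.
#' @param canny a \code{\link{cannyConfig}} used to binarize candidates.
#' @return list with \code{d1, d2, a1, a2}, the adjusted \code{field}, the
#'   achieved \code{fitness} and the non-decreasing best-so-far \code{trace}.
#' @export
mayflyOptimize <- function(field, config = mayflyConfig(), fitness = NULL,
                           canny = cannyConfig()) {
  stopifnot(is(field, "GradientField"))
  if (all(field@magnitude == 0))
    stop("degenerate input: gradient field is identically zero")
  if (is.null(fitness)) fitness <- edgeContinuityFitness
  bounds <- config$d_bounds
  if (is.null(bounds)) bounds <- c(0, 0.25 * max(field@magnitude))
  n <- config$swarm_size
  evaluate <- function(d1, d2, a1, a2) {
    px <- field@px + d1 * a1
    py <- field@py + d2 * a2
    f2 <- gradient_field(px, py)
    em <- edge_map_from_field(f2, canny)
    list(fit = fitness(em, f2), field = f2,
         coef = c(d1 = d1, d2 = d2, a1 = a1, a2 = a2))
  }
  with_seed(config$seed, {
    pos <- matrix(stats::runif(2 * n, bounds[1], bounds[2]), n, 2)
    vel <- matrix(0, n, 2)
    best <- NULL
    trace <- numeric(config$iterations)
    for (t in seq_len(config$iterations)) {
      for (i in seq_len(n)) {
        a <- stats::runif(2, -1, 1)
        cand <- evaluate(pos[i, 1], pos[i, 2], a[1], a[2])
        if (is.null(best) || cand$fit > best$fit) best <- cand
      }
      # drift toward the global best with random attraction (nuptial dance)
      for (i in seq_len(n)) {
        vel[i, ] <- 0.7 * vel[i, ] +
          1.5 * stats::runif(1) * (best$coef[c("d1", "d2")] - pos[i, ])
        pos[i, ] <- clamp(pos[i, ] + vel[i, ], bounds[1], bounds[2])
      }
      trace[t] <- best$fit
    }
    list(d1 = unname(best$coef["d1"]), d2 = unname(best$coef["d2"]),
         a1 = unname(best$coef["a1"]), a2 = unname(best$coef["a2"]),
         field = best$field, fitness = best$fit, trace = trace)
  })
}

#' Reference-free edge-continuity fitness
#'
#' Score in [0, 2]: the fraction of edge pixels having at least two edge
#' neighbors (8-connected) plus the mean gradient magnitude over edge
#' pixels normalized by the field maximum.  Rewards strong, unfragmented
#' contours without needing a ground-truth boundary.
#'
#' @param edge_map an \linkS4class{EdgeMap}.
#' @param field the \linkS4class{GradientField} the map came from.
#' @return numeric scalar in [0, 2].
#' @export
edgeContinuityFitness <- function(edge_map, field) {
  e <- maskMatrix(edge_map)
  if (!any(e)) return(0)
  nb <- conv2_rcpp(e * 1.0, matrix(1, 3, 3), 0L) - e
  frac2 <- mean(nb[e] >= 2)
  mm <- max(field@magnitude)
  strength <- if (mm > 0) mean(field@magnitude[e]) / mm else 0
  frac2 + strength
}

#' Pratt figure of merit of an edge map
#'
#' \deqn{FOM = \frac{1}{\max(N_d, N_t)} \sum_{i=1}^{N_d}
#'   \frac{1}{1 + d_i^2 / 9}}
#' with \eqn{d_i} the distance from each detected pixel to the nearest true
#' boundary pixel (scaling constant 1/9).  1 is a perfect match.
#'
#' @param edge_map an \linkS4class{EdgeMap} or logical matrix.
#' @param truth logical matrix of true boundary pixels.
#' @return numeric scalar in (0, 1].
#' @export
prattFigureOfMerit <- function(edge_map, truth) {
  e <- if (is(edge_map, "EdgeMap")) maskMatrix(edge_map) else edge_map
  det <- which(e, arr.ind = TRUE)
  tru <- which(truth, arr.ind = TRUE)
  nd <- nrow(det); nt <- nrow(tru)
  if (nt == 0L) stop("truth boundary is empty")
  if (nd == 0L) return(0)
  d2 <- vapply(seq_len(nd), function(i) {
    min((det[i, 1] - tru[, 1])^2 + (det[i, 2] - tru[, 2])^2)
  }, numeric(1))
  sum(1 / (1 + d2 / 9)) / max(nd, nt)
}

edge_map_from_field <- function(field, config) {
  nms <- non_max_suppress(field@px, field@py, field@magnitude)
  edges <- hysteresis(nms, max(field@magnitude),
                      config$low_frac, config$high_frac)
  new("EdgeMap", edges = edges, provenance = list(canny = unclass(config)))
}

#' Full adaptive Canny (Mayfly) edge detection
#'
#' Pipeline: LoG prefilter with image-of-interest retention, weighted-kernel
#' smoothing, Sobel-form gradients, optional Mayfly adjustment of the
#' gradient field, 4-direction non-maximum suppression, and double-threshold
#' hysteresis.  Output is a thin binary edge map; constant images yield an
#' empty map.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param config a \code{\link{cannyConfig}}.
#' @param mayfly a \code{\link{mayflyConfig}}, or NULL to skip the swarm
#'   adjustment.
#' @param fitness optional fitness for the Mayfly stage.
#' @return an \linkS4class{EdgeMap} with provenance.
#' @export
detectEdges <- function(image, config = cannyConfig(), mayfly = NULL,
                        fitness = NULL) {
  stopifnot(is(image, "GrayImage"))
  ioi <- logFilter(image, config$log_sigma)
  sm <- smoothImage(ioi, config)
  field <- computeGradients(sm)
  prov <- list(canny = unclass(config))
  if (!is.null(mayfly) && any(field@magnitude > 0)) {
    opt <- mayflyOptimize(field, mayfly, fitness = fitness, canny = config)
    field <- opt$field
    prov$mayfly <- c(unclass(mayfly)[c("swarm_size", "iterations", "seed")],
                     opt[c("d1", "d2", "a1", "a2", "fitness")])
  }
  em <- edge_map_from_field(field, config)
  new("EdgeMap", edges = maskMatrix(em), provenance = prov)
}

#' Segment the region of interest enclosed by an edge map
#'
#' Closes small gaps in the edge map (morphological closing with a small
#' disk), fills enclosed background regions, and returns the largest filled
#' component.  When nothing is enclosed the result is the documented empty
#' ROI signal (all-FALSE mask, with a message), not an error.
#'
#' @param image the source \linkS4class{GrayImage} (shape check only).
#' @param edges an \linkS4class{EdgeMap}.
#' @param close_radius disk radius for the closing, pixels.
#' @return a \linkS4class{RoiMask}.
#' @export
segmentRoi <- function(image, edges, close_radius = 1L) {
  stopifnot(is(image, "GrayImage"), is(edges, "EdgeMap"))
  e <- maskMatrix(edges)
  if (!identical(dim(e), dim(pixels(image))))
    stop("edge map and image shapes differ")
  if (!any(e)) {
    message("segmentRoi: empty edge map, returning empty ROI")
    return(new("RoiMask", mask = e))
  }
  se <- disk_se(close_radius)
  closed <- morph_rcpp(morph_rcpp(e, se, FALSE), se, TRUE)
  filled <- fill_holes_rcpp(closed)
  if (sum(filled) <= sum(closed)) {
    message("segmentRoi: edge map encloses no region, returning empty ROI")
    return(new("RoiMask", mask = e & FALSE))
  }
  new("RoiMask", mask = largest_component(filled))
}
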