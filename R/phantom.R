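#' Specification of a synthetic brain phantom
#'
#' Describes one synthetic 2-D "brain slice": a bright skull ring enclosing a
#' mid-intensity brain ellipse that contains a single tumor disk whose
#' interior carries a class-specific second-order texture (a sinusoidal
#' grating).  The three default texture parameterizations (period 2 / 4 / 8
#' pixels) stand in for the three tumor classes the pipeline discriminates
#' (meningioma / glioma / pituitary) and are chosen so their co-occurrence
#' contrast values at distance 1 differ pairwise by at least a factor 2.
#'
#' @param image_size pixels per side of the square image (>= 32).
#' @param skull_thickness thickness of the skull ring, pixels.
#' @param brain_axes ellipse semi-axes (row, column), pixels; defaults scale
#'   with the image.
#' @param tumor_class integer in 1..3 selecting the texture class.
#' @param tumor_radius tumor disk radius, pixels.
#' @param tumor_center disk center (row, col) offsets from the image center;
#'   default \code{c(0, 0)}.
#' @param texture_params list of three per-class lists with entries
#'   \code{period}, \code{amplitude}, \code{orientation} (degrees).
#' @param noise list with \code{salt_pepper_fraction} in [0,1] and
#'   \code{gaussian_sigma} >= 0.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"PhantomSpec"}.
#' @examples
#' spec <- phantomSpec(image_size = 64, tumor_class = 2)
#' ph <- generatePhantom(spec)
#' sum(ph$masks$tumor)
#' @export
phantomSpec <- function(image_size = 128L,
                        skull_thickness = 4L,
                        brain_axes = NULL,
                        tumor_class = 1L,
                        tumor_radius = NULL,
                        tumor_center = c(0, 0),
                        texture_params = defaultTextureParams(),
                        noise = list(salt_pepper_fraction = 0.01,
                                     gaussian_sigma = 5),
                        seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stop("image_size must be >= 32")
  if (is.null(brain_axes))
    brain_axes <- round(c(0.34, 0.28) * image_size)
  if (is.null(tumor_radius))
    tumor_radius <- max(6L, round(image_size / 9))
  spec <- list(image_size = image_size,
               skull_thickness = as.integer(skull_thickness),
               brain_axes = as.numeric(brain_axes),
               tumor_class = as.integer(tumor_class),
               tumor_radius = as.numeric(tumor_radius),
               tumor_center = as.numeric(tumor_center),
               texture_params = texture_params,
               noise = noise,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

#' Default per-class tumor texture parameters
#'
#' Sinusoidal gratings with class periods 2, 4 and 8 pixels.  Amplitudes are
#' fixed so that, noise-free, the SGLDM contrast at distance 1 differs
#' pairwise between classes by a factor >= 2 (the separability invariant the
#' downstream feature extractor relies on).
#'
#' @return list of three lists (period, amplitude, orientation in degrees).
#' @export
defaultTextureParams <- function() {
  list(list(period = 2, amplitude = 60, orientation = 0),
       list(period = 4, amplitude = 45, orientation = 0),
       list(period = 8, amplitude = 50, orientation = 0))
}

validatePhantomSpec <- function(spec) {
  s <- spec$image_size
  half <- (s - 1) / 2
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  gap <- 2
  if (spec$skull_thickness < 1L)
    stop("skull_thickness must be >= 1")
  if (a + gap + spec$skull_thickness + 1 > half ||
      b + gap + spec$skull_thickness + 1 > half)
    stop("brain_axes plus skull ring do not fit inside image_size ",
         "(offending fields: brain_axes / skull_thickness / image_size)")
  if (!(spec$tumor_class %in% 1:3)) stop("tumor_class must be 1, 2 or 3")
  r <- spec$tumor_radius
  dc <- spec$tumor_center
  # conservative containment: disk inside shrunken ellipse
  if (a - r <= 0 || b - r <= 0 ||
      (dc[1] / (a - r))^2 + (dc[2] / (b - r))^2 > 1)
    stop("tumor disk does not lie strictly inside brain ellipse ",
         "(offending fields: tumor_radius / tumor_center)")
  nz <- spec$noise
  if (nz$salt_pepper_fraction < 0 || nz$salt_pepper_fraction > 1)
    stop("salt_pepper_fraction must be in [0, 1]")
  if (nz$gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  invisible(TRUE)
}

# intensity levels of the phantom's structures
.phantom_levels <- list(background = 15, brain = 120, skull = 230,
                        tumor_base = 140)

#' Generate one synthetic brain phantom
#'
#' Renders the skull ring, brain ellipse and textured tumor disk described by
#' a \code{\link{phantomSpec}}, applies Gaussian then salt-and-pepper noise
#' under the spec's seed, and returns the 8-bit image together with exact
#' ground-truth masks.  Identical spec and seed give bit-identical output.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{image} (a \linkS4class{GrayImage}) and
#'   \code{masks} (logical matrices \code{skull}, \code{brain},
#'   \code{tumor}).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  validatePhantomSpec(spec)
  s <- spec$image_size
  ctr <- (s + 1) / 2
  rows <- matrix(seq_len(s) - ctr, s, s)
  cols <- matrix(seq_len(s) - ctr, s, s, byrow = TRUE)
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  gap <- 2
  ell <- (rows / a)^2 + (cols / b)^2
  brain <- ell <= 1
  inner <- (rows / (a + gap))^2 + (cols / (b + gap))^2
  outer_ <- (rows / (a + gap + spec$skull_thickness))^2 +
            (cols / (b + gap + spec$skull_thickness))^2
  skull <- outer_ <= 1 & inner > 1
  tc <- spec$tumor_center
  tumor <- (rows - tc[1])^2 + (cols - tc[2])^2 <= spec$tumor_radius^2

  lv <- .phantom_levels
  img <- matrix(lv$background, s, s)
  img[brain] <- lv$brain
  img[skull] <- lv$skull
  tp <- spec$texture_params[[spec$tumor_class]]
  th <- tp$orientation * pi / 180
  # cosine grating (pi/2 phase) on the integer pixel grid so a period-2
  # pattern alternates +A/-A instead of sampling its zeros (the centered
  # coordinates are half-integers for even sizes); orientation 0 varies
  # along columns, the mu = 0 co-occurrence direction
  ci <- matrix(seq_len(s), s, s, byrow = TRUE)
  ri <- matrix(seq_len(s), s, s)
  phase <- 2 * pi * (ci * cos(th) + ri * sin(th)) / tp$period + pi / 2
  tex <- lv$tumor_base + tp$amplitude * sin(phase)
  img[tumor] <- tex[tumor]
  img <- round(clamp(img, 0, 255))

  nz <- spec$noise
  if (nz$gaussian_sigma > 0 || nz$salt_pepper_fraction > 0) {
    img <- with_seed(spec$seed, {
      x <- img
      if (nz$gaussian_sigma > 0)
        x <- x + matrix(stats::rnorm(s * s, 0, nz$gaussian_sigma), s, s)
      if (nz$salt_pepper_fraction > 0) {
        n_sp <- round(nz$salt_pepper_fraction * s * s)
        if (n_sp > 0) {
          idx <- sample.int(s * s, n_sp)
          x[idx] <- ifelse(stats::runif(n_sp) < 0.5, 0, 255)
        }
      }
      x
    })
    img <- round(clamp(img, 0, 255))
  }
  list(image = GrayImage(img, range = c(0, 255)),
       masks = list(skull = skull, brain = brain, tumor = tumor))
}

#' Generate a balanced labeled phantom dataset
#'
#' Produces \code{3 * n_per_class} phantoms with per-image seeds derived
#' deterministically from the master seed.  Tumor position and radius are
#' jittered within the containment bounds and the texture orientation is
#' jittered uniformly over [0, 180) degrees.
#'
#' @param n_per_class images per tumor class (>= 1).
#' @param spec_template a \code{\link{phantomSpec}} used as template.
#' @param seed master seed.
#' @return a \linkS4class{LabeledImageSet}.
#' @export
generateImageDataset <- function(n_per_class, spec_template = phantomSpec(),
                                 seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  images <- list(); labels <- integer(0); masks <- list()
  idx <- 0L
  for (k in 1:3) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sd_i <- derive_seed(seed, idx)
      jit <- with_seed(sd_i, {
        list(radius_mult = stats::runif(1, 0.8, 1.2),
             center_frac = stats::runif(2, -0.3, 0.3),
             orientation = stats::runif(1, 0, 180))
      })
      spec <- spec_template
      spec$tumor_class <- k
      spec$seed <- derive_seed(sd_i, 1L)
      spec$tumor_radius <- spec_template$tumor_radius * jit$radius_mult
      a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
      r <- spec$tumor_radius
      spec$tumor_center <- c(jit$center_frac[1] * (a - r),
                             jit$center_frac[2] * (b - r)) * 0.9
      spec$texture_params[[k]]$orientation <- jit$orientation
      ph <- generatePhantom(spec)
      images[[idx]] <- ph$image
      masks[[idx]] <- ph$masks
      labels[idx] <- k
    }
  }
  new("LabeledImageSet", images = images, labels = labels, masks = masks)
}

#' Generate a synthetic feature table with planted informative columns
#'
#' Test harness for the feature-selection stage: informative columns are
#' class-conditional Gaussians (unit SD) whose class means span
#' \code{effect_size} SD units — evenly spaced levels with the extreme
#' classes separated by \code{effect_size}, assigned to classes by a fresh
#' random permutation per column so the columns carry complementary
#' information.  Noise columns are class-independent standard Gaussians.
#' Column order is shuffled; the ground-truth informative index set is
#' returned.  (With 5 informative columns at effect 3, a nearest-centroid
#' classifier on the informative block alone sits near 95 percent training
#' accuracy: adjacent class centroids are sqrt(5) * 1.5 SD apart.)
#'
#' @param n_samples total rows (>= 1); classes are balanced.
#' @param n_informative,n_noise column counts (>= 1 each).
#' @param class_count number of classes (>= 2).
#' @param effect_size between-class mean separation in SD units (> 0).
#' @param seed integer seed.
#' @return list with \code{features} (matrix with named columns),
#'   \code{labels} (integer), \code{informative} (integer column indices).
#' @export
generateFeatureTable <- function(n_samples, n_informative, n_noise,
                                 class_count = 3L, effect_size = 3,
                                 seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_informative <- as.integer(n_informative)
  n_noise <- as.integer(n_noise)
  class_count <- as.integer(class_count)
  if (min(n_samples, n_informative, n_noise) < 1L)
    stop("n_samples, n_informative and n_noise must be >= 1")
  if (class_count < 2L) stop("class_count must be >= 2")
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("effect_size must be > 0")
  with_seed(seed, {
    labels <- rep_len(seq_len(class_count), n_samples)
    d <- n_informative + n_noise
    x <- matrix(stats::rnorm(n_samples * d), n_samples, d)
    for (j in seq_len(n_informative)) {
      # per-column random assignment of evenly spaced mean levels spanning
      # effect_size SD units
      lev <- (sample(seq_len(class_count)) - 1L) / (class_count - 1L)
      x[, j] <- x[, j] + effect_size * lev[labels]
    }
    ord <- sample.int(d)
    x <- x[, ord, drop = FALSE]
    colnames(x) <- sprintf("F%02d", seq_len(d))
    informative <- match(seq_len(n_informative), ord)
    list(features = x, labels = labels, informative = sort(informative))
  })
}

#' Write a labeled phantom dataset to disk
#'
#' Images and masks are written as ASCII PGM (masks as 0/255) plus one JSON
#' sidecar listing labels, per-image files and the generation parameters.
#'
#' @param dataset a \linkS4class{LabeledImageSet}.
#' @param dir output directory (created if missing).
#' @param sidecar list of generation parameters recorded in the JSON.
#' @return invisibly, the sidecar path.
#' @export
writeImageDataset <- function(dataset, dir, sidecar = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset@images)
  files <- character(n)
  for (i in seq_len(n)) {
    f <- sprintf("img_%03d.pgm", i)
    writePgm(dataset@images[[i]], file.path(dir, f))
    for (m in names(dataset@masks[[i]])) {
      writePgm(dataset@masks[[i]][[m]] * 255,
               file.path(dir, sprintf("img_%03d_mask_%s.pgm", i, m)))
    }
    files[i] <- f
  }
  meta <- c(list(labels = dataset@labels, files = files), sidecar)
  path <- file.path(dir, "dataset.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
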