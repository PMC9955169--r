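#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities.
#' @param range declared intensity bounds, default the 8-bit range.
#' @param clip if TRUE, clamp pixels into \code{range} instead of erroring.
#' @return a \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(0:24, 5, 5), range = c(0, 255))
#' dim(pixels(img))
#' @export
GrayImage <- function(pixels, range = c(0, 255), clip = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (clip) pixels <- pmin(pmax(pixels, range[1]), range[2])
  new("GrayImage", pixels = pixels, range = as.numeric(range))
}

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname valueRange
#' @export
setMethod("valueRange", "GrayImage", function(x) x@range)

#' @describeIn GrayImage image dimensions (rows, columns).
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d, declared range [%g, %g]\n",
              nrow(p), ncol(p), object@range[1], object@range[2]))
  cat(sprintf("  intensities: min %.3g, median %.3g, max %.3g\n",
              min(p), stats::median(p), max(p)))
})

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "EdgeMap", function(x) x@edges)

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "RoiMask", function(x) x@mask)

#' @rdname isEmptyRoi
#' @export
setMethod("isEmptyRoi", "RoiMask", function(x) !any(x@mask))

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap %d x %d with %d edge pixels\n",
              nrow(object@edges), ncol(object@edges), sum(object@edges)))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask %d x %d with %d ROI pixels%s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              if (!any(object@mask)) " (empty ROI)" else ""))
})

setMethod("show", "LabeledImageSet", function(object) {
  cat(sprintf("LabeledImageSet of %d images; class counts: %s\n",
              length(object@images),
              paste(tabulate(object@labels, 3L), collapse = "/")))
})

# ---- plain-text image I/O ---------------------------------------------------

#' Write a grayscale image as ASCII PGM (P2)
#'
#' PGM is the always-available plain-text interchange format of this package;
#' PNG output is supported through the optional \pkg{png} package.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param path output file path.
#' @export
writePgm <- function(image, path) {
  p <- if (is(image, "GrayImage")) pixels(image) else as.matrix(image)
  maxv <- 255L
  q <- round(pmin(pmax(p, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxv)), con)
  # one image row per line, row-major as PGM expects
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path file path.
#' @return a \linkS4class{GrayImage} with range c(0, maxval).
#' @export
readPgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only ASCII PGM (P2) is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  GrayImage(matrix(vals, nrow = h, ncol = w, byrow = TRUE),
            range = c(0, maxv))
}

#' Write a grayscale image to PGM or (if available) PNG
#'
#' Dispatches on the file extension; \code{.png} requires the \pkg{png}
#' package and falls back to PGM (with a warning) when it is missing.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param path output path ending in \code{.pgm} or \code{.png}.
#' @export
writeImage <- function(image, path) {
  p <- if (is(image, "GrayImage")) pixels(image) else as.matrix(image)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(pmin(pmax(p / 255, 0), 1), target = path)
      return(invisible(path))
    }
    warning("png package unavailable; writing PGM instead")
    path <- sub("\\.png$", ".pgm", path, ignore.case = TRUE)
  }
  writePgm(p, path)
}

#' Read a grayscale image from PGM or (if available) PNG
#' @param path input path.
#' @return a \linkS4class{GrayImage} in the 0..255 range.
#' @export
readImage <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the png package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    return(GrayImage(a * 255, range = c(0, 255)))
  }
  readPgm(path)
}
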