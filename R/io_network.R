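#' Save a residual network as JSON
#'
#' Weights and configuration are written as plain JSON (full double
#' precision), so checkpoints are text and portable.  Practical for
#' feature-mode networks; image-mode checkpoints can be large.
#'
#' @param network a \linkS4class{ResidualNetwork}.
#' @param path output file.
#' @export
saveNetwork <- function(network, path) {
  stopifnot(is(network, "ResidualNetwork"))
  ser_layers <- function(layers) lapply(layers, function(ly) {
    out <- ly
    if (!is.null(ly$W)) {
      out$W <- as.vector(ly$W)
      out$W_dim <- dim(ly$W)
    }
    if (ly$type == "resblock") {
      out$branch <- ser_layers(ly$branch)
      if (!is.null(ly$shortcut)) out$shortcut <- ser_layers(ly$shortcut)
    }
    out
  })
  obj <- list(mode = network@mode, config = network@config,
              trained = network@trained,
              layers = ser_layers(network@layers))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a residual network from JSON
#' @param path file written by \code{\link{saveNetwork}}.
#' @return a \linkS4class{ResidualNetwork}.
#' @export
loadNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de_layers <- function(layers) lapply(layers, function(ly) {
    if (!is.null(ly$W)) {
      ly$W <- matrix(unlist(ly$W), ly$W_dim[[1]], ly$W_dim[[2]])
      ly$W_dim <- NULL
      ly$b <- as.numeric(unlist(ly$b))
    }
    if (identical(ly$type, "resblock")) {
      ly$branch <- de_layers(ly$branch)
      if (!is.null(ly$shortcut)) ly$shortcut <- de_layers(ly$shortcut)
    }
    for (f in c("k", "c_in", "c_out", "stride", "pad"))
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    ly
  })
  new("ResidualNetwork", mode = obj$mode,
      config = obj$config, trained = isTRUE(obj$trained),
      layers = de_layers(obj$layers))
}
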