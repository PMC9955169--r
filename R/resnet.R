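#' Residual network configuration
#'
#' Image mode follows the canonical 152-layer residual architecture: a 7x7
#' stride-2 stem, 3x3 max-pool, four bottleneck stages with widths
#' [64,64,256] x3, [128,128,512] x8, [256,256,1024] x36, [512,512,2048] x3,
#' global average pooling with dropout, and a softmax head of width
#' \code{class_count} (replacing the legacy 1000-way head).  Block counts
#' are scaled by \code{depth_scale} (ceiling, so no stage drops to zero) for
#' desk-scale runs.  Feature mode stacks residual fully-connected blocks of
#' the same transform-plus-shortcut form over a selected-feature vector.
#'
#' @param mode \code{"feature"} or \code{"image"}.
#' @param stage_spec list of four lists with \code{width} (bottleneck widths,
#'   length 3) and \code{blocks}.
#' @param depth_scale fraction in (0, 1] scaling block counts (ceiling).
#' @param dropout_rate dropout probability, default 0.5.
#' @param dropout_sites number of dropout sites distributed through the
#'   image-mode stack (the reference design uses 10).
#' @param class_count number of classes m (>= 2).
#' @param hidden_width feature-mode hidden width.
#' @param n_blocks feature-mode residual block count (also depth-scaled).
#' @param seed initialization seed.
#' @return list of class \code{"NetworkConfig"}.
#' @export
networkConfig <- function(mode = c("feature", "image"),
                          stage_spec = defaultStageSpec(),
                          depth_scale = 1,
                          dropout_rate = 0.5,
                          dropout_sites = 10L,
                          class_count = 3L,
                          hidden_width = 64L,
                          n_blocks = 3L,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (depth_scale <= 0) stop("depth_scale must be > 0 (zero blocks)")
  class_count <- as.integer(class_count)
  if (class_count < 2L) stop("class_count must be >= 2")
  structure(list(mode = mode, stage_spec = stage_spec,
                 depth_scale = depth_scale,
                 dropout_rate = dropout_rate,
                 dropout_sites = as.integer(dropout_sites),
                 class_count = class_count,
                 hidden_width = as.integer(hidden_width),
                 n_blocks = as.integer(n_blocks),
                 seed = as.integer(seed)),
            class = "NetworkConfig")
}

#' Default bottleneck stage specification (the 152-layer layout)
#' @return list of four (width, blocks) stages.
#' @export
defaultStageSpec <- function() {
  list(list(width = c(64, 64, 256), blocks = 3L),
       list(width = c(128, 128, 512), blocks = 8L),
       list(width = c(256, 256, 1024), blocks = 36L),
       list(width = c(512, 512, 2048), blocks = 3L))
}

scaled_blocks <- function(config) {
  n <- vapply(config$stage_spec, function(s) as.integer(s$blocks), 1L)
  out <- as.integer(ceiling(n * config$depth_scale))
  if (any(out < 1L)) stop("depth_scale yields a zero-block stage")
  out
}

#' Architecture summary without allocating weights
#'
#' Computes, from the configuration alone, the per-stage block counts after
#' depth scaling and the spatial output sizes for a given square input
#' (image mode).  The unscaled default reports blocks (3, 8, 36, 3) — 150
#' bottleneck convolutions plus stem and head — and sizes 56, 28, 14, 7 for
#' a 224 input.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param input_size square input side, default 224.
#' @return data.frame with stage, blocks, width_out, output_size.
#' @export
describeNetwork <- function(config, input_size = 224L) {
  stopifnot(inherits(config, "NetworkConfig"))
  blocks <- scaled_blocks(config)
  conv_out <- function(sz, k, s, p) floor((sz + 2 * p - k) / s) + 1L
  stem <- conv_out(input_size, 7L, 2L, 3L)
  pool <- conv_out(stem, 3L, 2L, 1L)
  sizes <- integer(4)
  sz <- pool
  for (s in 1:4) {
    if (s > 1) sz <- conv_out(sz, 1L, 2L, 0L)  # stride-2 projection
    sizes[s] <- sz
  }
  data.frame(stage = paste0("conv", 2:5),
             blocks = blocks,
             width_out = vapply(config$stage_spec,
                                function(s) s$width[3], numeric(1)),
             output_size = sizes)
}

# ---- layer constructors -----------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

layer_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(he_init(d_in, d_in * d_out), d_in, d_out),
       b = numeric(d_out))
}

layer_conv <- function(k, c_in, c_out, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  fan_in <- k * k * c_in
  list(type = "conv", k = as.integer(k), c_in = c_in, c_out = c_out,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(he_init(fan_in, fan_in * c_out), fan_in, c_out),
       b = numeric(c_out))
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
layer_gap <- function() list(type = "gap")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)

resblock_feature <- function(width) {
  list(type = "resblock",
       branch = list(layer_relu(), layer_dense(width, width),
                     layer_relu(), layer_dense(width, width)),
       shortcut = NULL)
}

resblock_image <- function(c_in, width, stride = 1L) {
  w1 <- width[1]; w2 <- width[2]; w3 <- width[3]
  branch <- list(layer_conv(1L, c_in, w1, stride = stride, pad = 0L),
                 layer_relu(),
                 layer_conv(3L, w1, w2, stride = 1L, pad = 1L),
                 layer_relu(),
                 layer_conv(1L, w2, w3, stride = 1L, pad = 0L))
  shortcut <- if (stride != 1L || c_in != w3)
    list(layer_conv(1L, c_in, w3, stride = stride, pad = 0L)) else NULL
  list(type = "resblock", branch = branch, shortcut = shortcut)
}

#' Build a residual network
#'
#' Seeded weight initialization (He).  Image mode: stem, max-pool, four
#' bottleneck stages (stride-2 projection shortcuts at stage transitions),
#' global average pooling, dropout, softmax head.  Feature mode: a dense
#' input projection, residual fully-connected blocks, dropout and the
#' softmax head.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param input_dim feature-mode input length, or image-mode input side
#'   (square images, single channel).
#' @return a \linkS4class{ResidualNetwork}.
#' @export
buildNetwork <- function(config, input_dim) {
  stopifnot(inherits(config, "NetworkConfig"))
  with_seed(config$seed, {
    layers <- list()
    if (config$mode == "feature") {
      nb <- max(1L, as.integer(ceiling(config$n_blocks * config$depth_scale)))
      h <- config$hidden_width
      layers <- c(layers, list(layer_dense(as.integer(input_dim), h)))
      for (b in seq_len(nb))
        layers <- c(layers, list(resblock_feature(h)))
      layers <- c(layers, list(layer_relu(),
                               layer_dropout(config$dropout_rate),
                               layer_dense(h, config$class_count)))
    } else {
      blocks <- scaled_blocks(config)
      stem_w <- config$stage_spec[[1]]$width[1]
      layers <- c(layers, list(layer_conv(7L, 1L, stem_w, stride = 2L,
                                          pad = 3L),
                               layer_relu(), layer_maxpool()))
      c_in <- stem_w
      total <- sum(blocks)
      sites <- max(1L, min(config$dropout_sites, total))
      drop_after <- unique(round(seq_len(sites - 1L) * total / sites))
      bi <- 0L
      for (s in 1:4) {
        w <- config$stage_spec[[s]]$width
        for (b in seq_len(blocks[s])) {
          stride <- if (s > 1L && b == 1L) 2L else 1L
          layers <- c(layers, list(resblock_image(c_in, w, stride)))
          c_in <- w[3]
          bi <- bi + 1L
          if (bi %in% drop_after)
            layers <- c(layers, list(layer_dropout(config$dropout_rate)))
        }
      }
      layers <- c(layers, list(layer_relu(), layer_gap(),
                               layer_dropout(config$dropout_rate),
                               layer_dense(c_in, config$class_count)))
    }
    new("ResidualNetwork", mode = config$mode, config = unclass(config),
        layers = layers, trained = FALSE)
  })
}

setMethod("show", "ResidualNetwork", function(object) {
  cat(sprintf("ResidualNetwork (%s mode), %d top-level layers%s\n",
              object@mode, length(object@layers),
              if (object@trained) ", trained" else ""))
})

# ---- forward / backward -----------------------------------------------------

# im2col index cache: maps output-position x kernel-offset to padded linear
# indices; built once per (shape, kernel, stride, pad)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  top <- (oi - 1L) * stride
  left <- (oj - 1L) * stride
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  base <- outer(top, ki, "+") + Hp * (outer(left, kj, "+") - 1L)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  for (c in seq_len(C))
    idx[, ((c - 1L) * k * k + 1L):(c * k * k)] <- base + (c - 1L) * Hp * Wp
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_array <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# forward one layer; x is a matrix (n x d) or a list of (H,W,C) arrays
layer_forward <- function(layer, x, train, ctx) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$W, 2L, layer$b, "+")
      list(out = out, cache = list(x = x))
    },
    relu = {
      out <- if (is.list(x)) lapply(x, function(a) pmax(a, 0)) else pmax(x, 0)
      list(out = out, cache = list(x = x))
    },
    dropout = {
      if (!train || layer$rate <= 0) return(list(out = x, cache = NULL))
      make_mask <- function(a)
        array(stats::runif(length(a)) >= layer$rate, dim(a) %||% length(a))
      if (is.list(x)) {
        masks <- lapply(x, make_mask)
        out <- mapply(function(a, m) a * m / (1 - layer$rate),
                      x, masks, SIMPLIFY = FALSE)
      } else {
        masks <- matrix(stats::runif(length(x)) >= layer$rate,
                        nrow(x), ncol(x))
        out <- x * masks / (1 - layer$rate)
      }
      list(out = out, cache = list(masks = masks))
    },
    conv = {
      caches <- vector("list", length(x))
      out <- vector("list", length(x))
      d <- dim(x[[1]])
      im <- im2col_index(d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      for (s in seq_along(x)) {
        xp <- pad_array(x[[s]], layer$pad)
        patches <- matrix(as.vector(xp)[im$idx], nrow(im$idx), ncol(im$idx))
        y <- sweep(patches %*% layer$W, 2L, layer$b, "+")
        out[[s]] <- array(y, c(im$Ho, im$Wo, layer$c_out))
        caches[[s]] <- patches
      }
      list(out = out, cache = list(patches = caches, im = im,
                                   in_dim = d))
    },
    maxpool = {
      d <- dim(x[[1]])
      im <- im2col_index(d[1], d[2], 1L, layer$k, layer$stride, layer$pad)
      out <- vector("list", length(x))
      args <- vector("list", length(x))
      for (s in seq_along(x)) {
        y <- array(0, c(im$Ho, im$Wo, d[3]))
        am <- matrix(0L, nrow(im$idx), d[3])
        for (c in seq_len(d[3])) {
          xp <- matrix(-Inf, im$Hp, im$Wp)
          xp[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2])] <-
            x[[s]][, , c]
          patches <- matrix(as.vector(xp)[im$idx], nrow(im$idx))
          a <- max.col(patches, ties.method = "first")
          y[, , c] <- patches[cbind(seq_len(nrow(patches)), a)]
          am[, c] <- a
        }
        out[[s]] <- y
        args[[s]] <- am
      }
      list(out = out, cache = list(argmax = args, im = im, in_dim = d))
    },
    gap = {
      n <- length(x)
      C <- dim(x[[1]])[3]
      out <- matrix(0, n, C)
      for (s in seq_len(n)) out[s, ] <- apply(x[[s]], 3L, mean)
      list(out = out, cache = list(in_dim = dim(x[[1]]), n = n))
    },
    resblock = {
      br <- forward_layers(layer$branch, x, train, ctx)
      sc <- if (is.null(layer$shortcut)) list(out = x, caches = NULL)
            else forward_layers(layer$shortcut, x, train, ctx)
      out <- if (is.list(br$out))
        mapply(`+`, br$out, sc$out, SIMPLIFY = FALSE)
      else br$out + sc$out
      list(out = out, cache = list(branch = br$caches,
                                   shortcut = sc$caches))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout, layers_grads_env = NULL) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$W),
           grads = list(W = t(cache$x) %*% dout, b = colSums(dout)))
    },
    relu = {
      x <- cache$x
      dx <- if (is.list(x))
        mapply(function(a, d) d * (a > 0), x, dout, SIMPLIFY = FALSE)
      else dout * (x > 0)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) return(list(dx = dout, grads = NULL))
      m <- cache$masks
      dx <- if (is.list(dout))
        mapply(function(d, mm) d * mm / (1 - layer$rate), dout, m,
               SIMPLIFY = FALSE)
      else dout * m / (1 - layer$rate)
      list(dx = dx, grads = NULL)
    },
    conv = {
      im <- cache$im
      d <- cache$in_dim
      dW <- matrix(0, nrow(layer$W), ncol(layer$W))
      db <- numeric(layer$c_out)
      dx <- vector("list", length(dout))
      plen <- im$Hp * im$Wp * d[3]
      iv <- as.vector(im$idx)
      for (s in seq_along(dout)) {
        dY <- matrix(dout[[s]], im$Ho * im$Wo, layer$c_out)
        patches <- cache$patches[[s]]
        dW <- dW + t(patches) %*% dY
        db <- db + colSums(dY)
        dpatch <- dY %*% t(layer$W)
        acc <- rowsum(as.vector(dpatch), iv)
        dxp <- numeric(plen)
        dxp[as.integer(rownames(acc))] <- acc
        dxp <- array(dxp, c(im$Hp, im$Wp, d[3]))
        dx[[s]] <- dxp[layer$pad + seq_len(d[1]),
                       layer$pad + seq_len(d[2]), , drop = FALSE]
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    maxpool = {
      im <- cache$im
      d <- cache$in_dim
      dx <- vector("list", length(dout))
      for (s in seq_along(dout)) {
        dxp <- array(0, c(im$Hp, im$Wp, d[3]))
        for (c in seq_len(d[3])) {
          a <- cache$argmax[[s]][, c]
          tgt <- im$idx[cbind(seq_along(a), a)]
          dv <- as.vector(dout[[s]][, , c])
          plane <- numeric(im$Hp * im$Wp)
          acc <- rowsum(dv, tgt)
          plane[as.integer(rownames(acc))] <- acc
          dxp[, , c] <- matrix(plane, im$Hp, im$Wp)
        }
        dx[[s]] <- dxp[layer$pad + seq_len(d[1]),
                       layer$pad + seq_len(d[2]), , drop = FALSE]
      }
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$in_dim
      hw <- d[1] * d[2]
      dx <- vector("list", cache$n)
      for (s in seq_len(cache$n)) {
        dx[[s]] <- array(rep(dout[s, ] / hw, each = hw), d)
      }
      list(dx = dx, grads = NULL)
    },
    resblock = {
      br <- backward_layers(layer$branch, cache$branch, dout)
      dsc <- if (is.null(layer$shortcut)) list(dx = dout, grads = NULL)
             else backward_layers(layer$shortcut, cache$shortcut, dout)
      dx <- if (is.list(br$dx))
        mapply(`+`, br$dx, dsc$dx, SIMPLIFY = FALSE)
      else br$dx + dsc$dx
      list(dx = dx, grads = list(branch = br$grads,
                                 shortcut = dsc$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

forward_layers <- function(layers, x, train, ctx = NULL) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train, ctx)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

backward_layers <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # [i] <- list(...) keeps NULL slots
  }
  list(dx = dout, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SGD + momentum over the (possibly nested) layer parameter structure
update_layers <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- layers[[i]]
    if (ly$type == "resblock") {
      rb <- update_layers(ly$branch, g$branch,
                          vel[[i]]$branch %||% vector("list",
                                                      length(ly$branch)),
                          lr, momentum)
      layers[[i]]$branch <- rb$layers
      vv <- list(branch = rb$vel, shortcut = NULL)
      if (!is.null(ly$shortcut)) {
        rs <- update_layers(ly$shortcut, g$shortcut,
                            vel[[i]]$shortcut %||% vector("list",
                                                          length(ly$shortcut)),
                            lr, momentum)
        layers[[i]]$shortcut <- rs$layers
        vv$shortcut <- rs$vel
      }
      vel[[i]] <- vv
    } else {
      v <- vel[[i]] %||% list(W = 0 * ly$W, b = 0 * ly$b)
      v$W <- momentum * v$W - lr * g$W
      v$b <- momentum * v$b - lr * g$b
      layers[[i]]$W <- ly$W + v$W
      layers[[i]]$b <- ly$b + v$b
      vel[[i]] <- v
    }
  }
  list(layers = layers, vel = vel)
}

# ---- exported functional ops ------------------------------------------------

#' Residual mapping with shortcut
#'
#' The residual unit \eqn{Z = K(x, G_i) + x}: applies the transform to the
#' input and adds the shortcut (identity by default).  With a zero transform
#' and identity shortcut the output equals the input exactly.
#'
#' @param x numeric input (vector, matrix or array).
#' @param transform function giving the residual mapping K; default the zero
#'   map.
#' @param shortcut function; default identity.
#' @return transform(x) + shortcut(x).
#' @export
residualBlock <- function(x, transform = function(x) 0 * x,
                          shortcut = identity) {
  tx <- transform(x)
  sx <- shortcut(x)
  if (!identical(dim(tx) %||% length(tx), dim(sx) %||% length(sx)))
    stop("configuration error: transform and shortcut shapes differ")
  tx + sx
}

#' Numerically stabilized softmax
#'
#' \eqn{S_i = e^{l_i} / \sum_j e^{l_j}} with max-subtraction, so outputs lie
#' in [0, 1] and always sum to one; invariant to adding a constant to all
#' logits.
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @return probabilities of the same shape.
#' @export
softmaxProbs <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    if (any(!is.finite(logits))) stop("logits must be finite")
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

#' Indicator cross-entropy loss
#'
#' The negated per-indicator log-likelihood
#' \deqn{u = -\frac{1}{N}\sum [z \log S + (1 - z)\log(1 - S)]}
#' averaged over all indicator entries (one-vs-rest expansion for m-class
#' probability matrices), with probabilities clipped to
#' \eqn{[\epsilon, 1-\epsilon]}, \eqn{\epsilon = 10^{-12}}.  Nonnegative;
#' 0 in the perfect-prediction limit; equals \eqn{\ln 2} when every
#' probability is 0.5.
#'
#' @param probabilities numeric vector of positive-class probabilities (with
#'   binary \code{labels}), or an n x m probability matrix (with class
#'   labels in 1..m, expanded one-vs-rest).
#' @param labels 0/1 indicators, or class indices for the matrix form.
#' @return scalar loss u >= 0.
#' @export
crossEntropyLoss <- function(probabilities, labels) {
  eps <- 1e-12
  if (is.matrix(probabilities)) {
    n <- nrow(probabilities)
    if (length(labels) != n) stop("length mismatch")
    z <- matrix(0, n, ncol(probabilities))
    z[cbind(seq_len(n), as.integer(labels))] <- 1
    s <- clamp(probabilities, eps, 1 - eps)
    -mean(z * log(s) + (1 - z) * log(1 - s))
  } else {
    if (length(labels) != length(probabilities)) stop("length mismatch")
    s <- clamp(probabilities, eps, 1 - eps)
    z <- as.numeric(labels)
    -mean(z * log(s) + (1 - z) * log(1 - s))
  }
}

# gradient of crossEntropyLoss + softmax wrt logits (matrix form)
softmax_bce_grad <- function(probs, labels) {
  n <- nrow(probs); m <- ncol(probs)
  eps <- 1e-12
  z <- matrix(0, n, m)
  z[cbind(seq_len(n), as.integer(labels))] <- 1
  s <- clamp(probs, eps, 1 - eps)
  dS <- -(z / s - (1 - z) / (1 - s)) / (n * m)
  # through the softmax jacobian
  probs * (dS - rowSums(dS * probs))
}

# ---- training and prediction ------------------------------------------------

#' Training configuration
#'
#' Optimizer defaults (stochastic gradient descent, momentum 0.9, learning
#' rate 1e-3, batch 16, 50 epochs) are conventional choices, all
#' configurable and recorded with the run.
#'
#' @param epochs,batch,learning_rate,momentum optimizer parameters.
#' @param seed shuffling/dropout seed.
#' @param validation_fraction held-out fraction monitored for the adaptive
#'   dropout anneal (0 disables the split; the training loss is monitored
#'   instead).
#' @param adaptive_dropout halve the dropout rate when the monitored loss
#'   plateaus (no improvement for \code{patience} epochs); FALSE keeps the
#'   rate fixed.
#' @param patience plateau length in epochs.
#' @return list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(epochs = 50L, batch = 16L, learning_rate = 1e-3,
                        momentum = 0.9, seed = 1L,
                        validation_fraction = 0,
                        adaptive_dropout = TRUE, patience = 3L) {
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 adaptive_dropout = isTRUE(adaptive_dropout),
                 patience = as.integer(patience)),
            class = "TrainConfig")
}

as_image_list <- function(x) {
  if (is.list(x))
    lapply(x, function(a) {
      p <- if (is(a, "GrayImage")) pixels(a) / 255 else a
      if (length(dim(p)) == 2L) array(p, c(dim(p), 1L)) else p
    })
  else stop("image-mode input must be a list of images")
}

set_dropout_rate <- function(layers, rate) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "dropout") layers[[i]]$rate <- rate
    if (layers[[i]]$type == "resblock") {
      layers[[i]]$branch <- set_dropout_rate(layers[[i]]$branch, rate)
      if (!is.null(layers[[i]]$shortcut))
        layers[[i]]$shortcut <- set_dropout_rate(layers[[i]]$shortcut, rate)
    }
  }
  layers
}

#' Train a residual network
#'
#' Minimizes the indicator cross-entropy (through the softmax head) by
#' seeded mini-batch stochastic gradient descent with momentum.  A
#' learning rate of 0 leaves the parameters unchanged.  Divergence
#' (non-finite loss) aborts with a diagnostic.
#'
#' @param network a \linkS4class{ResidualNetwork}.
#' @param x feature matrix (feature mode) or list of images (image mode).
#' @param y integer class labels in 1..class_count.
#' @param config a \code{\link{trainConfig}}.
#' @return list with the trained \code{network}, per-epoch mean training
#'   \code{trace}, and \code{dropout_trace} of effective rates.
#' @export
trainNetwork <- function(network, x, y, config = trainConfig()) {
  stopifnot(is(network, "ResidualNetwork"))
  y <- as.integer(y)
  m <- network@config$class_count
  if (any(y < 1L | y > m)) stop("labels out of range 1..class_count")
  feature_mode <- network@mode == "feature"
  if (feature_mode) x <- as.matrix(x) else x <- as_image_list(x)
  n <- if (feature_mode) nrow(x) else length(x)
  if (n == 0L) stop("empty dataset")
  layers <- network@layers
  vel <- vector("list", length(layers))
  trace <- numeric(config$epochs)
  rate <- network@config$dropout_rate
  drop_trace <- numeric(config$epochs)
  val_idx <- integer(0)
  with_seed(config$seed, {
    if (config$validation_fraction > 0) {
      val_idx <- sort(sample.int(n, max(1L, round(
        config$validation_fraction * n))))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    monitor_best <- Inf; stall <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch)) {
        bidx <- ord[start:min(start + config$batch - 1L, length(ord))]
        bx <- if (feature_mode) x[bidx, , drop = FALSE] else x[bidx]
        fw <- forward_layers(layers, bx, train = TRUE)
        probs <- softmaxProbs(fw$out)
        l <- crossEntropyLoss(probs, y[bidx])
        if (!is.finite(l))
          stop("training diverged: non-finite loss at epoch ", ep)
        losses <- c(losses, l)
        if (config$learning_rate > 0) {
          dlogits <- softmax_bce_grad(probs, y[bidx])
          bw <- backward_layers(layers, fw$caches, dlogits)
          up <- update_layers(layers, bw$grads, vel,
                              config$learning_rate, config$momentum)
          layers <- up$layers
          vel <- up$vel
        }
      }
      trace[ep] <- mean(losses)
      monitor <- if (length(val_idx) > 0) {
        vx <- if (feature_mode) x[val_idx, , drop = FALSE] else x[val_idx]
        vp <- softmaxProbs(forward_layers(layers, vx, train = FALSE)$out)
        crossEntropyLoss(vp, y[val_idx])
      } else trace[ep]
      if (config$adaptive_dropout) {
        if (monitor < monitor_best - 1e-6) {
          monitor_best <- monitor; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience && rate > 0.1) {
            rate <- rate / 2
            layers <- set_dropout_rate(layers, rate)
            stall <- 0L
          }
        }
      }
      drop_trace[ep] <- rate
    }
  })
  net <- new("ResidualNetwork", mode = network@mode,
             config = network@config, layers = layers, trained = TRUE)
  list(network = net, trace = trace, dropout_trace = drop_trace)
}

#' Class probabilities and prediction
#'
#' Forward pass in evaluation mode (dropout off); probabilities sum to one
#' and the predicted class is the argmax with lowest-index tie-break.
#'
#' @param network a \linkS4class{ResidualNetwork}.
#' @param x feature matrix or list of images, matching the network mode.
#' @return list with \code{probabilities} (n x m matrix) and \code{class}
#'   (integer vector).
#' @export
predictNetwork <- function(network, x) {
  stopifnot(is(network, "ResidualNetwork"))
  if (network@mode == "feature") {
    x <- as.matrix(x)
    if (ncol(x) != nrow(network@layers[[1]]$W))
      stop("input width does not match network input layer")
  } else x <- as_image_list(x)
  out <- forward_layers(network@layers, x, train = FALSE)$out
  probs <- softmaxProbs(out)
  list(probabilities = probs, class = max.col(probs, ties.method = "first"))
}
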