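#' Enhanced chimp optimization configuration
#'
#' @param swarm_size population size (>= 4, matching the four hunting roles
#'   of a chimp colony; the roles share one update rule here).
#' @param iterations number of iterations T (>= 1).
#' @param f_start,f_end endpoints of the control coefficient f, brought down
#'   from 2.5 to 0 nonlinearly over the run.
#' @param mode \code{"as_printed"} (the literal enhanced update, position =
#'   prey - 2 f cos(r2)(2 sin(r1) - 1)) or \code{"standard"} (the
#'   conventional chimp form position = prey - a3 * Dr with the sine/cosine
#'   coefficients).  Convergence-critical uses should pick
#'   \code{"standard"}.
#' @param bounds length-2 interval, or 2-column matrix (one row per
#'   dimension).
#' @param seed integer seed.
#' @param coef_form \code{"sincos"} (enhanced, a3 = 2 f sin(r1) - f,
#'   a1 = 2 cos(r2)) or \code{"linear"} (the unenhanced a3 = 2 f r1 - f,
#'   a1 = 2 r2); only meaningful in standard mode.
#' @return list of class \code{"ChoaConfig"}.
#' @export
choaConfig <- function(swarm_size = 20L, iterations = 30L,
                       f_start = 2.5, f_end = 0,
                       mode = c("as_printed", "standard"),
                       bounds = c(0, 1), seed = 1L,
                       coef_form = c("sincos", "linear")) {
  swarm_size <- as.integer(swarm_size)
  iterations <- as.integer(iterations)
  if (swarm_size < 4L) stop("swarm_size must be >= 4")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!(f_start > f_end)) stop("f_start must exceed f_end")
  structure(list(swarm_size = swarm_size, iterations = iterations,
                 f_start = f_start, f_end = f_end,
                 mode = match.arg(mode), bounds = bounds,
                 seed = as.integer(seed),
                 coef_form = match.arg(coef_form)),
            class = "ChoaConfig")
}

#' Nonlinear decay of the chimp control coefficient
#'
#' Quadratic ease-out from \code{f_start} (2.5) at t = 0 to \code{f_end}
#' (0) at t = T: \deqn{f(t) = f_{end} + (f_{start} - f_{end})(1 - t/T)^2.}
#' Monotone decreasing with exact endpoints.
#'
#' @param t current iteration in [0, T].
#' @param T total iterations (> 0).
#' @param f_start,f_end endpoints.
#' @return numeric f value.
#' @export
decayF <- function(t, T, f_start = 2.5, f_end = 0) {
  if (T <= 0) stop("T must be positive")
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  f_end + (f_start - f_end) * (1 - t / T)^2
}

#' Sine/cosine chimp coefficients
#'
#' The enhanced coefficient forms \eqn{a_3 = 2 f \sin(r_1) - f} and
#' \eqn{a_1 = 2 \cos(r_2)} (arguments in radians, r1 and r2 drawn uniformly
#' from [0, 1]).
#'
#' @param f control coefficient.
#' @param r1,r2 random draws in [0, 1] (vectors allowed).
#' @return list with components \code{a1} and \code{a3}.
#' @export
choaCoefficients <- function(f, r1, r2) {
  if (any(r1 < 0 | r1 > 1 | r2 < 0 | r2 > 1))
    stop("r1 and r2 must lie in [0, 1]")
  list(a1 = 2 * cos(r2), a3 = 2 * f * sin(r1) - f)
}

#' One chimp position update
#'
#' Given per-dimension random draws r1, r2 in [0,1] and a2 in [0,1]:
#' in \code{"as_printed"} mode the prey-distance
#' \eqn{D_r = |(2\cos(r_2) - f)\,S_{prey} - a_2 S_{chimp}|} is computed for
#' diagnostics and the new position is
#' \eqn{S_{prey} - [2 f \cos(r_2)(2\sin(r_1) - 1)]};
#' in \code{"standard"} mode \eqn{D_r = |a_1 S_{prey} - a_2 S_{chimp}|} and
#' the new position is \eqn{S_{prey} - a_3 D_r}.  The result is clamped to
#' the bounds.
#'
#' @param position current chimp position (numeric vector).
#' @param prey best-so-far position.
#' @param f control coefficient.
#' @param r1,r2,a2 per-dimension draws in [0, 1] (defaults drawn from the
#'   current RNG stream).
#' @param mode \code{"as_printed"} or \code{"standard"}.
#' @param bounds interval or per-dimension 2-column matrix.
#' @param coef_form \code{"sincos"} or \code{"linear"} (standard mode only).
#' @return updated position with attribute \code{"Dr"}.
#' @export
chimpStep <- function(position, prey, f,
                      r1 = stats::runif(length(position)),
                      r2 = stats::runif(length(position)),
                      a2 = stats::runif(length(position)),
                      mode = c("as_printed", "standard"),
                      bounds = c(-Inf, Inf),
                      coef_form = c("sincos", "linear")) {
  mode <- match.arg(mode)
  coef_form <- match.arg(coef_form)
  if (mode == "as_printed") {
    Dr <- abs((2 * cos(r2) - f) * prey - a2 * position)
    new_pos <- prey - (2 * f * cos(r2)) * (2 * sin(r1) - 1)
  } else {
    if (coef_form == "sincos") {
      a1 <- 2 * cos(r2)
      a3 <- 2 * f * sin(r1) - f
    } else {
      a1 <- 2 * r2
      a3 <- 2 * f * r1 - f
    }
    Dr <- abs(a1 * prey - a2 * position)
    new_pos <- prey - a3 * Dr
  }
  new_pos <- clamp_bounds(new_pos, bounds)
  attr(new_pos, "Dr") <- Dr
  new_pos
}

clamp_bounds <- function(x, bounds) {
  if (is.matrix(bounds)) clamp(x, bounds[, 1], bounds[, 2])
  else clamp(x, bounds[1], bounds[2])
}

#' Run the (enhanced) chimp optimizer
#'
#' Initializes positions uniformly within the bounds, then iterates the f
#' decay, per-chimp position updates, fitness evaluation and prey (global
#' best) update.  Candidates with non-finite fitness are rejected (the
#' chimp keeps its previous position); the best-so-far trace is
#' non-increasing.  Fully deterministic given the config seed.
#'
#' @param fitness function(numeric vector) -> scalar to minimize.
#' @param dim dimensionality (>= 1).
#' @param config a \code{\link{choaConfig}}.
#' @return list with \code{position}, \code{fitness}, per-iteration
#'   \code{trace}, and \code{rejected} (count of non-finite candidates).
#' @export
choaOptimize <- function(fitness, dim, config = choaConfig()) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1")
  b <- config$bounds
  if (!is.matrix(b)) b <- matrix(rep(b, each = dim), dim, 2)
  with_seed(config$seed, {
    n <- config$swarm_size
    pos <- sapply(seq_len(dim), function(d)
      stats::runif(n, b[d, 1], b[d, 2]))
    pos <- matrix(pos, n, dim)
    fit <- apply(pos, 1L, fitness)
    ok <- is.finite(fit)
    rejected <- sum(!ok)
    if (!any(ok)) stop("no finite fitness among initial positions")
    best_i <- which.min(ifelse(ok, fit, Inf))
    prey <- pos[best_i, ]; prey_fit <- fit[best_i]
    trace <- numeric(config$iterations)
    for (t in seq_len(config$iterations)) {
      f <- decayF(t, config$iterations, config$f_start, config$f_end)
      for (i in seq_len(n)) {
        cand <- chimpStep(pos[i, ], prey, f, mode = config$mode,
                          bounds = b, coef_form = config$coef_form)
        cf <- fitness(as.numeric(cand))
        if (!is.finite(cf)) { rejected <- rejected + 1L; next }
        pos[i, ] <- cand
        if (cf < prey_fit) { prey <- as.numeric(cand); prey_fit <- cf }
      }
      trace[t] <- prey_fit
    }
    list(position = prey, fitness = prey_fit, trace = trace,
         rejected = rejected)
  })
}

#' Wrapper objective configuration for feature selection
#'
#' @param omega weight of the classification error versus the subset-size
#'   penalty; the objective is
#'   \code{omega * cv_error + (1 - omega) * n_selected / n_features}.
#' @param k neighbors of the k-nearest-neighbor wrapper classifier.
#' @param folds stratified cross-validation folds.
#' @param max_n cap on the rows used by the wrapper fitness (stratified
#'   subsample, seeded) so selection stays desk-scale on augmented sets.
#' @return list of class \code{"WrapperConfig"}.
#' @export
wrapperConfig <- function(omega = 0.99, k = 5L, folds = 5L, max_n = 300L) {
  structure(list(omega = omega, k = as.integer(k),
                 folds = as.integer(folds), max_n = as.integer(max_n)),
            class = "WrapperConfig")
}

#' Wrapper feature selection by enhanced chimp optimization
#'
#' Continuous positions in [0,1]^D are mapped to inclusion masks by
#' thresholding at 0.5; the fitness of a mask is
#' \code{omega * (stratified k-fold CV error of a k-NN classifier on the
#' included, standardized features) + (1 - omega) * |mask| / D}.  Empty
#' masks are repaired by including the single highest-position feature, so
#' the result never selects nothing.
#'
#' @param features numeric matrix (rows = samples), no missing values.
#' @param labels class labels (>= 2 classes).
#' @param config a \code{\link{choaConfig}}; defaults to standard mode on
#'   [0,1] bounds (selection is convergence-critical).
#' @param wrapper a \code{\link{wrapperConfig}}.
#' @return a \linkS4class{SelectionMask}.
#' @export
selectFeatures <- function(features, labels,
                           config = choaConfig(mode = "standard"),
                           wrapper = wrapperConfig()) {
  features <- as.matrix(features)
  labels <- as.integer(factor(labels))
  if (any(!is.finite(features))) stop("features contain missing values")
  if (length(unique(labels)) < 2L)
    stop("labels must contain at least 2 classes")
  D <- ncol(features)
  if (D < 2L) stop("need at least 2 features")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  # standardize once
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  # stratified subsample for the wrapper fitness
  n <- nrow(x)
  sub <- with_seed(derive_seed(config$seed, 1L), {
    if (n <= wrapper$max_n) seq_len(n)
    else {
      take <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        m <- max(2L, round(length(ix) * wrapper$max_n / n))
        sample(ix, min(length(ix), m))
      }))
      sort(take)
    }
  })
  xs <- x[sub, , drop = FALSE]
  ys <- labels[sub]
  fold_id <- with_seed(derive_seed(config$seed, 2L),
                       stratified_folds(ys, wrapper$folds))
  mask_from_position <- function(pos) {
    m <- pos > 0.5
    if (!any(m)) m[which.max(pos)] <- TRUE
    m
  }
  fitness <- function(pos) {
    m <- mask_from_position(pos)
    err <- knn_cv_error(xs[, m, drop = FALSE], ys, wrapper$k, fold_id)
    wrapper$omega * err + (1 - wrapper$omega) * sum(m) / D
  }
  cfg <- config
  cfg$bounds <- c(0, 1)
  res <- choaOptimize(fitness, D, cfg)
  inc <- mask_from_position(res$position)
  names(inc) <- colnames(features)
  new("SelectionMask", included = inc, fitness = res$fitness,
      provenance = list(choa = unclass(cfg), wrapper = unclass(wrapper),
                        seed = config$seed))
}

#' @rdname includedFeatures
#' @export
setMethod("includedFeatures", "SelectionMask", function(x) x@included)

setMethod("show", "SelectionMask", function(object) {
  cat(sprintf("SelectionMask: %d of %d features, fitness %.4f\n",
              sum(object@included), length(object@included),
              object@fitness))
})

# ---- internal k-NN with stratified cross-validation -------------------------

# deterministic stratified fold assignment (uses the current RNG stream)
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  id
}

# majority-vote k-NN error over precomputed folds; ties break to the
# lowest class index
knn_cv_error <- function(x, y, k, fold_id) {
  err <- 0L
  n <- length(y)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    tr <- !te
    d2 <- sq_dist(x[te, , drop = FALSE], x[tr, , drop = FALSE])
    ytr <- y[tr]
    kk <- min(k, length(ytr))
    pred <- apply(d2, 1L, function(row) {
      nb <- ytr[order(row)[seq_len(kk)]]
      tab <- tabulate(nb)
      which.max(tab)
    })
    err <- err + sum(pred != y[te])
  }
  err / n
}

sq_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}
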