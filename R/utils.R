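# internal helpers: seeded RNG scoping, seed derivation, Otsu threshold

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a master seed; kept strictly below 2^31.
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.numeric(i)) %% 2147483629 + 1)
}

# Otsu's threshold on a numeric matrix; returns the intensity cut.
otsu_threshold <- function(p, range = c(0, 255), nbins = 256L) {
  br <- seq(range[1], range[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(p, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Disk structuring element of integer radius r (odd square logical matrix).
disk_se <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  d <- 2L * r + 1L
  idx <- seq_len(d) - r - 1L
  outer(idx, idx, function(i, j) i^2 + j^2 <= r^2 + 1e-9)
}

# Largest connected component of a logical matrix (8-connected by default).
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components_rcpp(mask, as.integer(connectivity))
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
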