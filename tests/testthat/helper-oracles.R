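# Independent brute-force oracles, deliberately naive: plain double loops,
# no shared code with the package implementations they check.

# pair-enumeration co-occurrence oracle
oracle_glcm <- function(q, Xg, v, mu, roi = NULL, symmetric = TRUE) {
  off <- switch(as.character(mu),
                "0" = c(0, v), "45" = c(-v, v), "90" = c(-v, 0),
                "135" = c(-v, -v))
  nr <- nrow(q); nc <- ncol(q)
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  counts <- matrix(0, Xg, Xg)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!roi[r, c] || !roi[r2, c2]) next
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts
}

# double-loop Haralick feature oracle over a normalized matrix
oracle_features <- function(p) {
  n <- nrow(p)
  energy <- contrast <- entropy <- homog <- dissim <- 0
  mu_i <- mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- var_j <- covar <- 0
  for (i in 1:n) for (j in 1:n) {
    pij <- p[i, j]
    energy <- energy + pij^2
    contrast <- contrast + ((i - 1) - (j - 1))^2 * pij
    if (pij > 0) entropy <- entropy - pij * log(pij)
    homog <- homog + pij / (1 + ((i - 1) - (j - 1))^2)
    dissim <- dissim + abs((i - 1) - (j - 1)) * pij
    var_i <- var_i + ((i - 1) - mu_i)^2 * pij
    var_j <- var_j + ((j - 1) - mu_j)^2 * pij
    covar <- covar + ((i - 1) - mu_i) * ((j - 1) - mu_j) * pij
  }
  corr <- if (var_i <= 1e-15 || var_j <= 1e-15) 1
          else covar / sqrt(var_i * var_j)
  c(energy = energy, contrast = contrast, entropy = entropy,
    homogeneity = homog, correlation = corr, variance = var_i,
    maximum_probability = max(p), dissimilarity = dissim)
}

# distances from each TRUE pixel of `a` to the nearest TRUE pixel of `b`
min_dists <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  vapply(seq_len(nrow(pa)), function(i)
    sqrt(min((pa[i, 1] - pb[, 1])^2 + (pa[i, 2] - pb[, 2])^2)),
    numeric(1))
}

# same, in Chebyshev (8-neighborhood) distance
min_dists_chebyshev <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  vapply(seq_len(nrow(pa)), function(i)
    min(pmax(abs(pa[i, 1] - pb[, 1]), abs(pa[i, 2] - pb[, 2]))),
    numeric(1))
}
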