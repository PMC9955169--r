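test_that("the control coefficient decays nonlinearly from 2.5 to 0", {
  expect_error(decayF(0, 0), "positive")
  expect_equal(decayF(0, 100), 2.5)
  expect_equal(decayF(100, 100), 0)
  expect_equal(decayF(50, 100), 0.625)      # 2.5 * 0.5^2
  f <- decayF(0:100, 100)
  expect_true(all(diff(f) < 0))
})

test_that("sine/cosine coefficients follow their closed forms", {
  expect_equal(choaCoefficients(0, 0.5, 0.5)$a3, 0)
  expect_equal(choaCoefficients(1, 0.5, 0)$a1, 2)    # cos 0 = 1
  expect_equal(choaCoefficients(1, 0, 0.3)$a3, -1)   # 2*1*0 - 1
  expect_error(choaCoefficients(1, 1.5, 0), "r1")
})

test_that("the position update matches hand arithmetic in both modes", {
  # as-printed update at f = 0 collapses onto the prey
  p <- chimpStep(0.3, 1.0, f = 0, r1 = 0.2, r2 = 0.9, a2 = 0.4,
                 mode = "as_printed")
  expect_equal(as.numeric(p), 1.0)
  # frozen hand-computed value:
  # 1.0 - [2 * 1 * cos(0.5)] * (2 * sin(0.5) - 1)
  #   = 1.0 - 1.7551651 * (-0.0411490) = 1.0722232
  p2 <- chimpStep(0.5, 1.0, f = 1, r1 = 0.5, r2 = 0.5, a2 = 0.3,
                  mode = "as_printed")
  expect_equal(as.numeric(p2), 1.0722232, tolerance = 1e-7)
  expect_equal(as.numeric(attr(p2, "Dr")),
               abs((2 * cos(0.5) - 1) * 1.0 - 0.3 * 0.5))
  # standard mode at f = 0: a3 = 0, so the position lands on the prey
  p3 <- chimpStep(0.3, 1.0, f = 0, r1 = 0.7, r2 = 0.1, a2 = 0.6,
                  mode = "standard")
  expect_equal(as.numeric(p3), 1.0)
  # standard mode with linear coefficients reduces to the published update
  r1 <- 0.3; r2 <- 0.8; a2 <- 0.25; f <- 1.7
  p4 <- chimpStep(0.4, 0.9, f, r1, r2, a2, mode = "standard",
                  coef_form = "linear")
  Dr <- abs(2 * r2 * 0.9 - a2 * 0.4)
  expect_equal(as.numeric(p4), 0.9 - (2 * f * r1 - f) * Dr)
})

test_that("the optimizer is elitist, bounded and deterministic", {
  sphere <- function(x) sum(x^2)
  cfg <- choaConfig(swarm_size = 10, iterations = 40, mode = "standard",
                    bounds = c(-5, 5), seed = 17)
  r1 <- choaOptimize(sphere, 3, cfg)
  r2 <- choaOptimize(sphere, 3, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$trace) <= 1e-12))
  expect_true(all(abs(r1$position) <= 5))
  # as-printed mode: elitist trace for several seeds
  for (s in 1:5) {
    tr <- choaOptimize(sphere, 3,
                       choaConfig(swarm_size = 8, iterations = 25,
                                  mode = "as_printed", bounds = c(-5, 5),
                                  seed = s))$trace
    expect_true(all(diff(tr) <= 1e-12))
  }
  # non-finite fitness candidates are rejected, not propagated
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  rr <- choaOptimize(spiky, 2, choaConfig(swarm_size = 8, iterations = 10,
                                          bounds = c(-5, 5), seed = 2,
                                          mode = "standard"))
  expect_true(is.finite(rr$fitness))
  expect_gt(rr$rejected, 0)
})

test_that("standard mode solves small continuous problems", {
  # 1-D quadratic: |x - 3| <= 0.1 in at least 18 of 20 seeds
  hits <- sum(vapply(1:20, function(s) {
    r <- choaOptimize(function(x) (x - 3)^2, 1,
                      choaConfig(swarm_size = 20, iterations = 60,
                                 mode = "standard", bounds = c(0, 10),
                                 seed = s))
    abs(r$position - 3) <= 0.1
  }, logical(1)))
  expect_gte(hits, 18)
})

test_that("feature selection recovers a planted perfect feature", {
  set.seed(55)
  x <- matrix(rnorm(150 * 8), 150, 8)
  y <- rep(1:2, length.out = 150)
  x[, 3] <- y * 10 + rnorm(150, 0, 0.01)   # feature 3 equals the label
  colnames(x) <- paste0("f", 1:8)
  hits <- vapply(1:10, function(s) {
    m <- selectFeatures(x, y, choaConfig(swarm_size = 10, iterations = 15,
                                         mode = "standard", seed = s))
    includedFeatures(m)[["f3"]]
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("selection guards its preconditions and never returns empty", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(selectFeatures(x, rep(1, 20)), "2 classes")
  expect_error(selectFeatures(x[, 1, drop = FALSE], rep(1:2, 10)),
               "2 features")
  xx <- cbind(x, NA)
  expect_error(selectFeatures(xx, rep(1:2, 10)), "missing")
  # empty-mask repair: even with pure noise some feature is included
  m <- selectFeatures(x, rep(1:2, 10),
                      choaConfig(swarm_size = 6, iterations = 5,
                                 mode = "standard", seed = 1))
  expect_gte(sum(includedFeatures(m)), 1L)
})

test_that("a duplicated informative column does not inflate the selection", {
  tab <- generateFeatureTable(200, 3, 6, 2, 3, seed = 21)
  x <- tab$features
  xdup <- cbind(x, dup = x[, tab$informative[1]])
  sizes <- vapply(1:6, function(s) {
    cfg <- choaConfig(swarm_size = 12, iterations = 20, mode = "standard",
                      seed = s)
    c(sum(includedFeatures(selectFeatures(x, tab$labels, cfg))),
      sum(includedFeatures(selectFeatures(xdup, tab$labels, cfg))))
  }, numeric(2))
  expect_lte(mean(sizes[2, ] - sizes[1, ]), 1)
})
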