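test_that("quantization maps intensities to levels as defined", {
  expect_error(quantizeImage(GrayImage(matrix(0, 4, 4)), 1), "Xg")
  img <- GrayImage(matrix(c(0, 255, 128, 32, 100, 200, 64, 16, 255),
                          3, 3))
  q <- quantizeImage(img, 8)
  expect_equal(q[1, 1], 0L)                 # floor(0 * 8 / 256)
  expect_equal(q[2, 1], 7L)                 # floor(255 * 8 / 256) = 7
  expect_equal(q[3, 1], 4L)                 # floor(128 * 8 / 256)
  cst <- quantizeImage(GrayImage(matrix(40, 4, 4)), 8)
  expect_equal(length(unique(as.vector(cst))), 1L)
})

test_that("the 2x2 worked example matches hand enumeration", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)      # [[0,0],[1,1]] by rows
  attr(q, "Xg") <- 2L
  cm <- cooccurrence(q, v = 1, mu = 0, symmetric = TRUE)
  expect_equal(pairCounts(cm), matrix(c(2, 0, 0, 2), 2, 2))
  # 4 counts total, so each occupied cell carries probability 1/2
  # (probabilities must sum to 1)
  expect_equal(probabilities(cm), matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(probabilities(cm)), 1)
  # constant image: all mass on the diagonal cell
  qc <- matrix(3L, 4, 4); attr(qc, "Xg") <- 8L
  cmc <- cooccurrence(qc, v = 1, mu = 0)
  expect_equal(probabilities(cmc)[4, 4], 1)
})

test_that("co-occurrence equals brute-force pair enumeration (all v, mu)", {
  set.seed(2024)
  for (rep in 1:10) {
    q <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
    attr(q, "Xg") <- 8L
    roi <- if (rep %% 2 == 0) matrix(runif(256) > 0.3, 16, 16) else NULL
    for (v in 1:2) for (mu in c(0, 45, 90, 135)) {
      for (sym in c(TRUE, FALSE)) {
        got <- pairCounts(cooccurrence(q, roi, v, mu, symmetric = sym))
        expect_equal(got, oracle_glcm(q, 8, v, mu, roi, symmetric = sym))
      }
    }
  }
})

test_that("opposite offsets give transposed matrices when not symmetric", {
  set.seed(7)
  q <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
  attr(q, "Xg") <- 8L
  # 0 vs 180 degrees: reversing the offset swaps the pair roles, so the
  # transposed matrix counts (right, left) pairs — checked by direct tally
  a <- pairCounts(cooccurrence(q, v = 1, mu = 0, symmetric = FALSE))
  expect_equal(a[1, 2], sum(q[, -12] == 0 & q[, -1] == 1))
  expect_equal(t(a)[1, 2], sum(q[, -1] == 0 & q[, -12] == 1))
  # symmetric counting is the sum of both directions
  s <- pairCounts(cooccurrence(q, v = 1, mu = 0, symmetric = TRUE))
  expect_equal(s, a + t(a))
  # probabilities always sum to 1
  expect_equal(sum(probabilities(cooccurrence(q, v = 2, mu = 45))), 1)
  # degenerate ROI
  roi <- matrix(FALSE, 12, 12); roi[1, 1] <- TRUE
  expect_error(cooccurrence(q, roi, 1, 0), "degenerate")
})

test_that("texture features match the double-loop oracle", {
  # degenerate distribution: all mass at one cell
  p <- matrix(0, 4, 4); p[2, 2] <- 1
  suppressMessages(f <- textureFeatures(p))
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["maximum_probability"]], 1)
  # uniform over 16 cells
  u <- matrix(1 / 16, 4, 4)
  expect_equal(textureFeatures(u)[["energy"]], 1 / 16)
  # random matrices vs the independent oracle
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rexp(64), 8, 8); m <- m / sum(m)
    expect_equal(textureFeatures(m), oracle_features(m), tolerance = 1e-12)
  }
})

test_that("ROI feature vectors are stable, named and dimensioned", {
  ph <- generatePhantom(noise_free_spec(1, 64))
  cfg <- sgldmConfig(gray_levels = 8, distances = c(1, 2),
                     angles_deg = c(0, 45, 90, 135))
  f1 <- extractRoiFeatures(ph$image, ph$masks$tumor, cfg)
  expect_length(f1, 8L * 2L * 4L)
  expect_true(all(grepl("^v[12]\\.a(0|45|90|135)\\.", names(f1))))
  expect_identical(f1, extractRoiFeatures(ph$image, ph$masks$tumor, cfg))
  # feature separation between tumor classes (noise-free)
  ph2 <- generatePhantom(noise_free_spec(2, 64))
  f2 <- extractRoiFeatures(ph2$image, ph2$masks$tumor, cfg)
  expect_gte(f1[["v1.a0.contrast"]] / f2[["v1.a0.contrast"]], 2)
  expect_error(extractRoiFeatures(ph$image,
                                  new("RoiMask",
                                      mask = matrix(FALSE, 64, 64)), cfg),
               "empty")
})
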