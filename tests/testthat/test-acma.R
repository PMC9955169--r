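test_that("LoG prefilter retains the image of interest", {
  expect_error(logFilter(GrayImage(matrix(1, 8, 8)), sigma = 0), "sigma")
  cst <- GrayImage(matrix(9, 16, 16))
  expect_equal(pixels(logFilter(cst, 1)), matrix(9, 16, 16))  # LoG of const = 0
  # bright disk on dark field: the disk interior survives
  m <- matrix(5, 32, 32)
  disk <- outer(1:32, 1:32, function(r, c) (r - 16)^2 + (c - 16)^2 <= 64)
  m[disk] <- 200
  out <- pixels(logFilter(GrayImage(m), 1))
  core <- outer(1:32, 1:32, function(r, c) (r - 16)^2 + (c - 16)^2 <= 25)
  expect_true(all(out[core] == 200))
})

test_that("the beta-weighted smoothing kernel behaves per its definition", {
  expect_error(cannyConfig(beta = 0), "beta")
  expect_error(cannyConfig(low_frac = 0.3, high_frac = 0.2), "low_frac")
  cst <- GrayImage(matrix(5, 9, 9))
  expect_equal(pixels(smoothImage(cst, cannyConfig(beta = 2))),
               matrix(5, 9, 9))
  # unit impulse, beta = 2: kernel sum 10 -> neighbors 1/10, center 2/10
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- pixels(smoothImage(GrayImage(imp, range = c(0, 1)),
                            cannyConfig(beta = 2)))
  expect_equal(out[4:6, 4:6],
               matrix(c(1, 1, 1, 1, 2, 1, 1, 1, 1) / 10, 3, 3))
  expect_equal(sum(out), 1)
  # the default center weight is 2
  expect_equal(cannyConfig()$beta, 2)
})

test_that("gradient kernels, magnitude and direction follow the definitions", {
  cst <- computeGradients(GrayImage(matrix(3, 8, 8)))
  expect_true(all(cst@magnitude == 0))
  expect_true(all(cst@px == 0) && all(cst@py == 0))
  # vertical step 0 | 100: |px| = 400 on the boundary columns, py = 0 inside
  st <- matrix(0, 10, 10); st[, 6:10] <- 100
  g <- computeGradients(GrayImage(st))
  expect_equal(abs(g@px[5, 5]), 400)
  expect_equal(abs(g@px[5, 6]), 400)
  expect_true(all(g@py[3:8, ] == 0))
  expect_equal(g@alpha[5, 5], 90)   # |py| = 0 maps to 90 degrees
  # 3-4-5 under the square-root convention
  f <- NeuroTexNet:::gradient_field(matrix(3, 3, 3), matrix(4, 3, 3))
  expect_true(all(f@magnitude == 5))
  # alpha consistency: magnitude = 0 iff px = py = 0
  set.seed(1)
  r <- GrayImage(matrix(sample(0:255, 400, TRUE), 20, 20))
  gr <- computeGradients(r)
  expect_true(all(gr@magnitude >= 0))
  expect_identical(gr@magnitude == 0, gr@px == 0 & gr@py == 0)
})

test_that("detected edges trace the square phantom boundary", {
  sq <- square_phantom()
  em <- detectEdges(sq$image)
  e <- maskMatrix(em)
  # every edge pixel within 1 px (8-neighborhood) of the true boundary
  expect_true(all(min_dists_chebyshev(e, sq$boundary) <= 1))
  expect_gte(mean(min_dists(e, sq$boundary) <= 1), 0.9)     # precision
  expect_gte(mean(min_dists(sq$boundary, e) <= 1), 0.9)     # recall
  # thin: no 3x3 all-edge block
  blocks <- NeuroTexNet:::conv2_rcpp(e * 1.0, matrix(1, 3, 3), 0L)
  expect_lt(max(blocks), 9)
  # constant image -> empty map
  expect_equal(sum(maskMatrix(detectEdges(GrayImage(matrix(7, 32, 32))))), 0L)
})

test_that("90-degree rotation of the input rotates the edge set", {
  ph <- generatePhantom(phantomSpec(image_size = 64, tumor_class = 3,
                                    seed = 12))
  p <- pixels(ph$image)
  e1 <- maskMatrix(detectEdges(GrayImage(p)))
  p90 <- t(p[nrow(p):1, ])                      # exact array rotation
  e2 <- maskMatrix(detectEdges(GrayImage(p90)))
  e2back <- t(e2)[nrow(e2):1, ]                 # rotate the output back
  interior <- matrix(FALSE, 64, 64); interior[3:62, 3:62] <- TRUE
  expect_equal(e1[interior], e2back[interior])
})

test_that("the Mayfly stage is seeded, elitist and respects d = 0", {
  sq <- square_phantom()
  field <- computeGradients(smoothImage(logFilter(sq$image, 1)))
  # zero bounds: adjusted field equals the input field
  opt0 <- mayflyOptimize(field, mayflyConfig(swarm_size = 4, iterations = 3,
                                             d_bounds = c(0, 0), seed = 1))
  expect_equal(opt0$field@px, field@px)
  expect_equal(opt0$field@py, field@py)
  # elitism: best-so-far trace is non-decreasing; runs reproduce
  o1 <- mayflyOptimize(field, mayflyConfig(swarm_size = 6, iterations = 8,
                                           seed = 3))
  o2 <- mayflyOptimize(field, mayflyConfig(swarm_size = 6, iterations = 8,
                                           seed = 3))
  expect_true(all(diff(o1$trace) >= -1e-12))
  expect_identical(o1[c("d1", "d2", "a1", "a2", "fitness")],
                   o2[c("d1", "d2", "a1", "a2", "fitness")])
  # direction consistency: stored alpha reproduces from adjusted components
  expect_equal(o1$field@alpha,
               atan2(abs(o1$field@px), abs(o1$field@py)) * 180 / pi)
  # degenerate field
  zf <- NeuroTexNet:::gradient_field(matrix(0, 5, 5), matrix(0, 5, 5))
  expect_error(mayflyOptimize(zf), "degenerate")
})

test_that("ROI segmentation fills enclosed regions and signals empty maps", {
  img <- GrayImage(matrix(0, 41, 41))
  empty <- new("EdgeMap", edges = matrix(FALSE, 41, 41), provenance = list())
  expect_message(roi0 <- segmentRoi(img, empty), "empty")
  expect_true(isEmptyRoi(roi0))
  # closed circle of edge pixels -> filled disk of matching radius (+/- 1 px)
  th <- seq(0, 2 * pi, length.out = 400)
  circ <- matrix(FALSE, 41, 41)
  circ[cbind(round(21 + 14 * sin(th)), round(21 + 14 * cos(th)))] <- TRUE
  roi <- segmentRoi(img, new("EdgeMap", edges = circ, provenance = list()))
  disk_in <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 13^2)
  disk_out <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 15^2)
  expect_true(all(maskMatrix(roi)[disk_in]))
  expect_true(all(!maskMatrix(roi)[!disk_out]))
  # phantom tumor boundary edges recover the tumor mask
  ph <- generatePhantom(noise_free_spec(3, 96))
  tumor <- ph$masks$tumor
  ring <- tumor & !NeuroTexNet:::morph_rcpp(tumor, NeuroTexNet:::disk_se(1L),
                                            TRUE)
  roi2 <- segmentRoi(ph$image, new("EdgeMap", edges = ring,
                                   provenance = list()))
  jac <- sum(maskMatrix(roi2) & tumor) / sum(maskMatrix(roi2) | tumor)
  expect_gte(jac, 0.8)
})

test_that("the Pratt figure of merit rewards exact boundaries", {
  sq <- square_phantom()
  perfect <- prattFigureOfMerit(sq$boundary, sq$boundary)
  expect_equal(perfect, 1)
  shifted <- rbind(sq$boundary[-1, ], FALSE)
  expect_lt(prattFigureOfMerit(shifted, sq$boundary), 1)
  expect_gt(prattFigureOfMerit(shifted, sq$boundary), 0.5)
})
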