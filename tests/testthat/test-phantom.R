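test_that("noise-free phantoms are deterministic and follow the texture", {
  spec <- noise_free_spec(2, 64)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$masks, b$masks)
  # tumor pixels follow the stated grating exactly: recompute the pattern
  tp <- spec$texture_params[[2]]
  s <- spec$image_size
  ci <- matrix(seq_len(s), s, s, byrow = TRUE)
  ri <- matrix(seq_len(s), s, s)
  expect_equal(tp$orientation, 0)
  tex <- round(pmin(pmax(
    140 + tp$amplitude * sin(2 * pi * ci / tp$period + pi / 2), 0), 255))
  tm <- a$masks$tumor
  expect_equal(pixels(a$image)[tm], tex[tm])
})

test_that("noisy phantom generation is seeded and bit-reproducible", {
  spec <- phantomSpec(image_size = 64, tumor_class = 1, seed = 99)
  expect_identical(pixels(generatePhantom(spec)$image),
                   pixels(generatePhantom(spec)$image))
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(pixels(generatePhantom(spec)$image),
                         pixels(generatePhantom(spec2)$image)))
})

test_that("phantom masks are geometrically consistent", {
  for (k in 1:3) {
    ph <- generatePhantom(phantomSpec(image_size = 96, tumor_class = k,
                                      seed = k))
    m <- ph$masks
    expect_equal(sum(m$skull & m$brain), 0L)   # skull disjoint from brain
    expect_true(all(m$brain[m$tumor]))         # tumor inside brain
    expect_identical(dim(m$brain), dim(pixels(ph$image)))
  }
})

test_that("ill-fitting geometry is rejected with the offending field named", {
  expect_error(phantomSpec(image_size = 31), "image_size")
  expect_error(phantomSpec(image_size = 64, brain_axes = c(40, 40)),
               "brain_axes")
  expect_error(phantomSpec(image_size = 64, tumor_radius = 30),
               "tumor_radius")
})

test_that("class textures separate by >= 2x SGLDM contrast at distance 1", {
  con <- vapply(1:3, function(k) {
    ph <- generatePhantom(noise_free_spec(k))
    q <- quantizeImage(ph$image, 8)
    cm <- cooccurrence(q, ph$masks$tumor, v = 1, mu = 0)
    # verified against the brute-force oracle
    expect_equal(pairCounts(cm),
                 oracle_glcm(q, 8, 1, 0, ph$masks$tumor))
    textureFeatures(cm)[["contrast"]]
  }, numeric(1))
  ratios <- c(con[1] / con[2], con[2] / con[3], con[1] / con[3])
  expect_true(all(ratios >= 2))
})

test_that("image datasets are balanced, jittered and reproducible", {
  spec <- phantomSpec(image_size = 64)
  d1 <- generateImageDataset(4, spec, seed = 7)
  d2 <- generateImageDataset(4, spec, seed = 7)
  expect_length(d1@images, 12L)
  expect_equal(tabulate(d1@labels, 3L), c(4L, 4L, 4L))
  expect_identical(lapply(d1@images, pixels), lapply(d2@images, pixels))
  # a different seed moves the tumors
  d3 <- generateImageDataset(4, spec, seed = 8)
  expect_false(identical(d1@masks[[1]]$tumor, d3@masks[[1]]$tumor))
  # n_per_class = 1 gives one image per class
  expect_equal(generateImageDataset(1, spec, seed = 1)@labels, 1:3)
})

test_that("feature tables plant recoverable structure", {
  expect_error(generateFeatureTable(100, 5, 20, 3, effect_size = 0),
               "effect_size")
  expect_error(generateFeatureTable(100, 5, 20, class_count = 1, 3),
               "class_count")
  tab <- generateFeatureTable(300, 5, 20, 3, 3, seed = 11)
  expect_equal(dim(tab$features), c(300L, 25L))
  expect_length(tab$informative, 5L)
  # nearest-centroid on the informative block alone: >= 95% train accuracy
  x <- tab$features[, tab$informative]
  cent <- vapply(1:3, function(k) colMeans(x[tab$labels == k, , drop = FALSE]),
                 numeric(5))
  d <- vapply(1:3, function(k) rowSums(sweep(x, 2, cent[, k])^2),
              numeric(300))
  expect_gte(mean(max.col(-d) == tab$labels), 0.95)
  # determinism
  expect_identical(tab$features,
                   generateFeatureTable(300, 5, 20, 3, 3, seed = 11)$features)
})

test_that("datasets round-trip through the PGM + JSON sidecar format", {
  dir <- withr::local_tempdir()
  ds <- generateImageDataset(1, phantomSpec(image_size = 48), seed = 3)
  writeImageDataset(ds, dir, sidecar = list(seed = 3))
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$labels, 1:3)
  back <- readPgm(file.path(dir, meta$files[2]))
  expect_equal(pixels(back), pixels(ds@images[[2]]))
})
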