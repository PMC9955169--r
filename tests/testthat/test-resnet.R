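test_that("softmax is a stabilized probability map", {
  expect_equal(softmaxProbs(rep(1, 4)), rep(0.25, 4))
  expect_equal(softmaxProbs(c(0, log(2))), c(1 / 3, 2 / 3))
  # shift invariance and unit sum even for extreme logits
  l <- c(1000, 1001, 999)
  expect_equal(softmaxProbs(l), softmaxProbs(l - 1000))
  expect_equal(sum(softmaxProbs(l)), 1, tolerance = 1e-9)
  m <- softmaxProbs(matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(m), rep(1, 3), tolerance = 1e-9)
})

test_that("the indicator cross-entropy has its closed-form values", {
  # perfect prediction limit -> 0
  expect_lt(crossEntropyLoss(rep(1 - 1e-13, 5), rep(1, 5)), 1e-10)
  # Si = 0.5 everywhere -> ln 2, in both vector and matrix forms
  expect_equal(crossEntropyLoss(rep(0.5, 8), rep(1, 8)), log(2))
  expect_equal(crossEntropyLoss(matrix(0.5, 4, 2), c(1, 2, 1, 2)), log(2))
  # moving any probability toward its label decreases the loss
  p <- c(0.3, 0.6); y <- c(1, 0)
  expect_lt(crossEntropyLoss(c(0.4, 0.5), y), crossEntropyLoss(p, y))
  expect_error(crossEntropyLoss(c(0.5, 0.5), 1), "mismatch")
})

test_that("loss gradient vanishes at a perfect one-hot optimum", {
  # numeric gradient of loss(softmax(logits)) at a sharply correct logit
  y <- c(1L, 2L, 3L)
  logits <- matrix(-40, 3, 3); diag(logits) <- 40
  g <- NeuroTexNet:::softmax_bce_grad(softmaxProbs(logits), y)
  expect_lt(max(abs(g)), 1e-10)
})

test_that("residual blocks are identities at zero transform", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(residualBlock(x), x)                   # zero transform
  expect_equal(residualBlock(x, transform = function(z) z * 0 + 2), x + 2)
  expect_error(residualBlock(x, transform = function(z) z[, 1:2]),
               "configuration")
  # a built feature-mode network with zeroed branches is an identity stack
  net <- buildNetwork(networkConfig(mode = "feature", hidden_width = 6,
                                    n_blocks = 2, class_count = 3,
                                    dropout_rate = 0, seed = 1),
                      input_dim = 6)
  layers <- net@layers
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "resblock") {
      for (j in seq_along(layers[[i]]$branch)) {
        if (!is.null(layers[[i]]$branch[[j]]$W)) {
          layers[[i]]$branch[[j]]$W <- layers[[i]]$branch[[j]]$W * 0
          layers[[i]]$branch[[j]]$b <- layers[[i]]$branch[[j]]$b * 0
        }
      }
      xin <- matrix(abs(rnorm(12)), 2, 6)
      out <- NeuroTexNet:::forward_layers(list(layers[[i]]), xin,
                                          train = FALSE)$out
      expect_identical(out, xin)
    }
  }
})

test_that("the unscaled architecture reproduces the reference table", {
  d <- describeNetwork(networkConfig(mode = "image"), input_size = 224)
  expect_equal(d$blocks, c(3L, 8L, 36L, 3L))
  expect_equal(d$output_size, c(56L, 28L, 14L, 7L))
  expect_equal(d$width_out, c(256, 512, 1024, 2048))
  # 50 bottleneck blocks = 150 convolutional layers plus stem and head
  expect_equal(sum(d$blocks), 50L)
  # the small test preset scales to (1, 1, 2, 1)
  d2 <- describeNetwork(networkConfig(mode = "image", depth_scale = 0.05))
  expect_equal(d2$blocks, c(1L, 1L, 2L, 1L))
  expect_error(networkConfig(depth_scale = 0), "depth_scale")
})

test_that("image-mode forward shapes follow the stage transitions", {
  cfg <- networkConfig(mode = "image", stage_spec = tiny_stage_spec(),
                       class_count = 3, dropout_rate = 0, seed = 2)
  net <- buildNetwork(cfg, input_dim = 32)
  # count bottleneck blocks and check a stride-2 projection halves the grid
  blocks <- Filter(function(l) l$type == "resblock", net@layers)
  expect_length(blocks, 5L)   # 1 + 1 + 2 + 1
  x <- list(array(runif(32 * 32), c(32, 32, 1)))
  out <- NeuroTexNet:::forward_layers(net@layers, x, train = FALSE)$out
  expect_equal(dim(out), c(1L, 3L))
  # spatial sizes: 32 -> stem 16 -> pool 8 -> stages 8, 4, 2, 1
  d <- describeNetwork(cfg, input_size = 32)
  expect_equal(d$output_size, c(8L, 4L, 2L, 1L))
})

test_that("training learns a separable feature problem; lr 0 is a no-op", {
  tab <- generateFeatureTable(240, 5, 10, 3, 3, seed = 7)
  x <- scale(tab$features)
  net <- buildNetwork(networkConfig(mode = "feature", class_count = 3,
                                    seed = 2), input_dim = ncol(x))
  fit <- trainNetwork(net, x, tab$labels, trainConfig(epochs = 40, seed = 3))
  pred <- predictNetwork(fit$network, x)
  expect_gte(mean(pred$class == tab$labels), 0.95)
  expect_lt(tail(fit$trace, 1), fit$trace[1])
  # learning rate 0: parameters unchanged, flat loss trace (dropout off so
  # the forward pass is deterministic; 240 samples split into equal batches)
  net0 <- buildNetwork(networkConfig(mode = "feature", class_count = 3,
                                     dropout_rate = 0, seed = 2),
                       input_dim = ncol(x))
  f0 <- trainNetwork(net0, x, tab$labels,
                     trainConfig(epochs = 3, learning_rate = 0, seed = 3,
                                 adaptive_dropout = FALSE))
  expect_identical(f0$network@layers[[1]]$W, net0@layers[[1]]$W)
  expect_equal(diff(range(f0$trace)), 0, tolerance = 1e-9)
  expect_error(trainNetwork(net, x, rep(9L, nrow(x)), trainConfig()),
               "labels")
})

test_that("a small convolutional network trains on an image contrast task", {
  set.seed(4)
  imgs <- lapply(1:40, function(i)
    matrix(runif(32 * 32) * 0.3 + ifelse(i <= 20, 0, 0.5), 32, 32))
  y <- rep(1:2, each = 20)
  cfg <- networkConfig(mode = "image", stage_spec = tiny_stage_spec(),
                       class_count = 2, dropout_rate = 0.2, seed = 1)
  net <- buildNetwork(cfg, input_dim = 32)
  fit <- trainNetwork(net, imgs, y,
                      trainConfig(epochs = 8, batch = 8,
                                  learning_rate = 0.01, seed = 5))
  pred <- predictNetwork(fit$network, imgs)
  expect_gte(mean(pred$class == y), 0.9)
  expect_lt(tail(fit$trace, 1), 0.5 * fit$trace[1])
})

test_that("prediction is deterministic with lowest-index tie-breaks", {
  net <- buildNetwork(networkConfig(mode = "feature", hidden_width = 8,
                                    class_count = 3, seed = 6),
                      input_dim = 4)
  x <- matrix(rnorm(8), 2, 4)
  p1 <- predictNetwork(net, x)
  p2 <- predictNetwork(net, rbind(x, x))
  expect_equal(p1$probabilities, p2$probabilities[1:2, ])
  expect_equal(rowSums(p1$probabilities), rep(1, 2), tolerance = 1e-9)
  # exact logit ties resolve to the lowest class index
  tie <- matrix(c(0.2, 0.5, 0.3, 0.5, 0.5, 0.0), 2, 3, byrow = TRUE)
  expect_equal(max.col(tie, ties.method = "first"), c(2L, 1L))
  expect_error(predictNetwork(net, matrix(0, 1, 7)), "width")
})

test_that("networks round-trip through the JSON checkpoint format", {
  dir <- withr::local_tempdir()
  net <- buildNetwork(networkConfig(mode = "feature", hidden_width = 5,
                                    n_blocks = 1, class_count = 3, seed = 9),
                      input_dim = 7)
  path <- file.path(dir, "model.json")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  x <- matrix(rnorm(21), 3, 7)
  expect_equal(predictNetwork(back, x)$probabilities,
               predictNetwork(net, x)$probabilities, tolerance = 1e-12)
})
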