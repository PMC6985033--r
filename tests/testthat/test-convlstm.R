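test_that("convolution arithmetic and feasibility checks", {
  expect_identical(convOutputLength(48, 6, 4), 28L)
  expect_identical(convOutputLength(48, 1, 4), 48L)
  expect_error(convOutputLength(24, 8, 4), "infeasible")
  expect_error(modelConfig(24, 10, kernelFrames = 8), "infeasible")
  expect_error(modelConfig(48, 0), "positive")
})

test_that("forward pass produces seeded, normalized probabilities", {
  cfg <- modelConfig(48, 135, kernelFrames = 6, convChannels = 8,
                     lstmCells = 12, nClasses = 14)
  net1 <- buildModel(cfg, seed = 5)
  net2 <- buildModel(cfg, seed = 5)
  expect_identical(net1@params, net2@params)
  expect_false(identical(net1@params, buildModel(cfg, seed = 6)@params))
  set.seed(1)
  X <- array(rnorm(20 * 48 * 135), c(20, 48, 135))
  p <- predictWindowProba(net1, X)
  expect_identical(dim(p), c(20L, 14L))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # identical windows give identical rows
  Xs <- X[rep(1, 3), , , drop = FALSE]
  ps <- predictWindowProba(net1, Xs)
  expect_identical(ps[1, ], ps[2, ])
  # channel mismatch is reported with the expected width
  expect_error(predictWindowProba(net1, X[, , 1:5]), "N = 135")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tinyModelConfig()
  net <- buildModel(cfg, seed = 7)
  set.seed(42)
  X <- array(rnorm(3 * 12 * 3), c(3, 12, 3))
  y <- c(1L, 3L, 2L)
  lossFn <- function(params)
    MotionScreen:::.crossEntropy(
      MotionScreen:::.nnForward(params, X, cfg)$probs, y)
  fwd <- MotionScreen:::.nnForward(net@params, X, cfg, keepCache = TRUE)
  gv <- unlist(MotionScreen:::.nnBackward(net@params, fwd, cfg, y))
  pv <- unlist(net@params)
  gn <- numeric(length(pv))
  eps <- 1e-6
  for (i in seq_along(pv)) {
    pp <- pv; pp[i] <- pp[i] + eps
    pm <- pv; pm[i] <- pm[i] - eps
    gn[i] <- (lossFn(utils::relist(pp, net@params)) -
              lossFn(utils::relist(pm, net@params))) / (2 * eps)
  }
  expect_lt(max(abs(gn - gv) / pmax(1e-6, abs(gn) + abs(gv))), 1e-4)
})

test_that("training is deterministic and inert at zero learning rate", {
  wd <- separableWindows()
  cfg <- tinyModelConfig(nClasses = 2L)
  net <- buildModel(cfg, vocabulary = wd@vocabulary, seed = 2)
  tc <- trainConfig(learningRate = 0.05, momentum = 0.9, batchSize = 10,
                    maxEpochs = 5, seed = 3)
  h1 <- trainingHistory(trainModel(net, wd, NULL, tc))
  h2 <- trainingHistory(trainModel(net, wd, NULL, tc))
  expect_identical(h1, h2)
  tc0 <- trainConfig(learningRate = 0, momentum = 0.9, batchSize = 10,
                     maxEpochs = 1, seed = 3)
  net0 <- trainModel(net, wd, NULL, tc0)
  expect_identical(net0@params, net@params)
})

test_that("loss is non-increasing over early epochs at a small rate", {
  wd <- separableWindows(nPerClass = 15L)
  cfg <- tinyModelConfig(nClasses = 2L)
  net <- buildModel(cfg, vocabulary = wd@vocabulary, seed = 4)
  tc <- trainConfig(learningRate = 0.002, momentum = 0, batchSize = 30,
                    maxEpochs = 5, seed = 5)
  h <- trainingHistory(trainModel(net, wd, NULL, tc))
  expect_true(all(diff(h$loss) <= 1e-6))
})

test_that("window order permutation leaves outputs valid", {
  wd <- separableWindows()
  cfg <- tinyModelConfig(nClasses = 2L)
  net <- buildModel(cfg, vocabulary = wd@vocabulary, seed = 2)
  tc <- trainConfig(learningRate = 0.05, momentum = 0.9, batchSize = 10,
                    maxEpochs = 3, seed = 3)
  perm <- rev(seq_along(wd@labelIdx))
  wdp <- new("WindowedDataset", windows = wd@windows[perm, , ],
             labelIdx = wd@labelIdx[perm], vocabulary = wd@vocabulary,
             starts = wd@starts, windowFrames = wd@windowFrames,
             strideFrames = wd@strideFrames)
  netp <- trainModel(net, wdp, NULL, tc)
  p <- predictWindowProba(netp, wd)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
})

test_that("stored fixture weights reproduce stored probabilities", {
  fix <- jsonlite::read_json(test_path("fixtures", "tiny-net.json"),
                             simplifyVector = TRUE)
  cfg <- modelConfig(fix$cfg$windowFrames, fix$cfg$inputChannels,
                     kernelFrames = fix$cfg$kernelFrames,
                     convChannels = fix$cfg$convChannels,
                     lstmCells = fix$cfg$lstmCells,
                     nClasses = fix$cfg$nClasses)
  net <- buildModel(cfg, seed = fix$seed)
  X <- array(fix$window, dim = c(1, fix$cfg$windowFrames,
                                 fix$cfg$inputChannels))
  p <- predictWindowProba(net, X)
  expect_equal(as.numeric(p), fix$probs, tolerance = 1e-6)
})
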