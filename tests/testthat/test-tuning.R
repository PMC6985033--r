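test_that("the default grids enumerate the full search spaces", {
  lg <- learningGrid()
  expect_identical(nrow(lg$grid), 25L)  # 5 learning rates x 5 momenta
  ag <- architectureGrid()
  combos <- enumerateArchitectureGrid(ag)
  expect_identical(nrow(combos), 36L)   # 4 window/kernel pairs x 3 x 3
  # kernel pairing: size 8 never with window 24, size 5 never with 48
  expect_false(any(combos$windowFrames == 24 & combos$kernelFrames == 8))
  expect_false(any(combos$windowFrames == 48 & combos$kernelFrames == 5))
  expect_setequal(unique(combos$kernelFrames[combos$windowFrames == 24]),
                  c(5, 6))
})

test_that("learning grid search returns the argmax of its score table", {
  wd <- separableWindows(nPerClass = 12L)
  vd <- separableWindows(nPerClass = 6L, seed = 2)
  cfg <- tinyModelConfig(nClasses = 2L)
  tc <- trainConfig(batchSize = 12, maxEpochs = 4, patience = 4, seed = 3)
  g <- learningGrid(learningRates = c(0.0001, 0.05), momenta = 0.9)
  res <- gridSearchLearning(g, cfg, wd, vd, tc)
  expect_identical(nrow(res$table), 2L)
  best <- res$table[which.max(res$table$valF1), ]
  expect_identical(res$best$learningRate, best$learningRate)
  # 1x1 grid returns its single point
  g1 <- learningGrid(learningRates = 0.05, momenta = 0.9)
  r1 <- gridSearchLearning(g1, cfg, wd, vd, tc)
  expect_identical(r1$best, list(learningRate = 0.05, momentum = 0.9))
})

test_that("diverging grid points are excluded from the argmax with a warning", {
  wd <- separableWindows(nPerClass = 10L)
  vd <- separableWindows(nPerClass = 5L, seed = 2)
  cfg <- tinyModelConfig(nClasses = 2L)
  tc <- trainConfig(batchSize = 20, maxEpochs = 3, patience = 3, seed = 3)
  g <- learningGrid(learningRates = c(0.05, Inf), momenta = 0.9)
  expect_warning(res <- gridSearchLearning(g, cfg, wd, vd, tc), "failed")
  expect_true(is.na(res$table$valF1[is.infinite(res$table$learningRate)]))
  expect_identical(res$best$learningRate, 0.05)
})

test_that("architecture search respects pairing and returns a feasible config", {
  set.seed(10)
  n <- 400
  vals <- matrix(rnorm(n * 2), n, 2)
  labs <- rep(rep(c("A", "B"), each = 25), 8)
  vals[labs == "B", 1] <- vals[labs == "B", 1] + 2
  tr <- list(values = vals[1:300, ], labels = labs[1:300])
  va <- list(values = vals[301:400, ], labels = labs[301:400])
  g <- architectureGrid(windowFrames = 12L,
                        kernelsByWindow = list(`12` = 2L),
                        convChannels = 4L, lstmCells = c(4L, 6L))
  tc <- trainConfig(learningRate = 0.05, batchSize = 25, maxEpochs = 3,
                    patience = 3, seed = 1)
  res <- gridSearchArchitecture(g, tr, va, c("A", "B", "Null"),
                                learningRate = 0.05, momentum = 0.9,
                                tcfg = tc)
  expect_identical(nrow(res$table), 2L)
  expect_s4_class(res$best, "ModelConfig")
  expect_identical(res$best@kernelFrames, 2L)
  bestRow <- res$table[which.max(res$table$valF1), ]
  expect_identical(res$best@lstmCells, as.integer(bestRow$lstmCells))
})
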