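test_that("athlete evaluation conserves frames and aggregates exactly", {
  fix <- smallSimuFixture()
  simu <- fix$simu
  vocab <- labelVocabulary(fix$cohort)
  byAth <- MotionScreen:::.groupByAthlete(simu)
  # train a small model on athletes 1-3, evaluate on athlete 4
  split <- list(train = names(byAth)[1:3], validation = character(),
                test = names(byAth)[4])
  mcfg <- modelConfig(24, 65, kernelFrames = 5, convChannels = 4,
                      lstmCells = 6, nClasses = 3)
  tcfg <- trainConfig(learningRate = 0.02, batchSize = 50, maxEpochs = 2,
                      seed = 6)
  res <- MotionScreen:::.trainAndEvaluate(simu, split, mcfg, tcfg, vocab)
  totalFrames <- sum(vapply(byAth[[split$test]], nFrames, integer(1)))
  expect_identical(res$report@nFrames, totalFrames)
  # aggregate micro-F1 equals pooled frame accuracy recomputed from labels
  ev <- res$perAthlete[[1]]
  acc <- mean(ev$predLabels == ev$trueLabels)
  expect_equal(unname(res$report@micro["f1"]), acc)
  # per-frame fused probabilities stay distributions
  expect_equal(rowSums(ev$probs), rep(1, nrow(ev$probs)), tolerance = 1e-9)
})

test_that("the prediction timeline plot writes an image file", {
  ev <- list(trueLabels = rep(c("Null", "STEPR", "Null"), c(30, 100, 30)),
             predLabels = rep(c("Null", "STEPR", "STEPL", "Null"),
                              c(25, 80, 25, 30)))
  f <- tempfile(fileext = ".png")
  plotPredictionTimeline(ev, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})

test_that("aggregating reports sums confusion matrices", {
  v <- c("A", "B")
  r1 <- precisionRecallF1(matrix(c(3L, 1L, 0L, 2L), 2, dimnames = list(v, v)))
  r2 <- precisionRecallF1(matrix(c(2L, 0L, 1L, 3L), 2, dimnames = list(v, v)))
  agg <- aggregateReports(list(r1, r2))
  expect_identical(agg@nFrames, 12L)
  expect_identical(agg@confusion["A", "A"], 5L)
  expect_equal(unname(agg@micro["f1"]), 10 / 12)
})

test_that("a model that memorized one athlete scores a perfect F1", {
  fix <- smallSimuFixture()
  byAth <- MotionScreen:::.groupByAthlete(fix$simu)
  vocab <- labelVocabulary(fix$cohort)
  one <- names(byAth)[1]
  split <- list(train = one, validation = character(), test = one)
  mcfg <- modelConfig(24, 15, kernelFrames = 5, convChannels = 8,
                      lstmCells = 12, nClasses = 3)
  tcfg <- trainConfig(learningRate = 0.05, batchSize = 30, maxEpochs = 150,
                      seed = 8)
  sub <- lapply(fix$simu, selectSensorConfig, configName = "sIMU3L")
  res <- MotionScreen:::.trainAndEvaluate(sub, split, mcfg, tcfg, vocab)
  # near-perfect: the residual errors sit on movement/null boundary frames
  # where overlapping windows carry mixed labels
  expect_gte(unname(res$report@micro["f1"]), 0.95)
})
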