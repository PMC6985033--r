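test_that("athlete split reproduces the published subset sizes", {
  ids <- sprintf("A%03d", 1:417)
  sp <- splitAthletes(ids, seed = 3)
  expect_length(sp$train, 278L)
  expect_length(sp$validation, 69L)
  expect_length(sp$test, 70L)
  # partition: disjoint and exhaustive
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
  # small cohort and determinism
  sp6 <- splitAthletes(sprintf("B%d", 1:6), seed = 5)
  expect_identical(lengths(sp6), c(train = 4L, validation = 1L, test = 1L))
  expect_identical(sp6, splitAthletes(sprintf("B%d", 1:6), seed = 5))
  expect_error(splitAthletes(c("a", "b")), "3 athletes")
})

test_that("normalization statistics standardize training data only", {
  set.seed(12)
  train <- cbind(rnorm(500, 3, 2), rnorm(500, -1, 0.5), rep(7, 500))
  stats <- fitNormalization(train)
  z <- applyNormalization(train, stats)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z[, 1:2], 2, sd) - 1)), 1e-9)
  # constant channel: sd floored, output identically zero
  expect_identical(max(abs(z[, 3])), 0)
  # validation data normalized with training stats keeps its shift
  val <- cbind(rnorm(200, 5, 2), rnorm(200, -1, 0.5), rep(7, 200))
  zv <- applyNormalization(val, stats)
  expect_gt(abs(mean(zv[, 1])), 0.5)
  expect_error(fitNormalization(train[1, , drop = FALSE]), "2 training")
})

test_that("trial concatenation preserves labels and records boundaries", {
  fix <- smallSimuFixture()
  s <- fix$simu[1:2]
  cat2 <- concatenateAthleteTrials(s)
  n1 <- nFrames(s[[1]])
  expect_identical(nFrames(cat2), n1 + nFrames(s[[2]]))
  expect_identical(S4Vectors::metadata(cat2)$boundaries, n1 + 1L)
  expect_identical(frameLabels(cat2),
                   c(frameLabels(s[[1]]), frameLabels(s[[2]])))
  expect_identical(concatenateAthleteTrials(s[1]), s[[1]])
  bad <- selectSensorConfig(s[[2]], "sIMU1")
  expect_error(concatenateAthleteTrials(list(s[[1]], bad)), "channel sets")
})

test_that("window geometry follows the count formula", {
  mat <- matrix(rnorm(96 * 2), 96, 2)
  labs <- rep(c("A", "Null"), c(50, 46))
  wd <- makeWindows(mat, 48, labels = labs)
  expect_identical(wd@strideFrames, 12L)
  expect_identical(wd@starts, c(1L, 13L, 25L, 37L, 49L))
  # property: count = floor((T - SWS)/stride) + 1 over random lengths
  set.seed(99)
  for (i in 1:20) {
    n <- sample(48:400, 1)
    wd <- makeWindows(matrix(0, n, 1), 48, labels = rep("A", n),
                      vocabulary = c("A", "Null"))
    expect_length(wd@starts, floor((n - 48) / 12) + 1)
  }
  expect_error(makeWindows(matrix(0, 40, 1), 48, labels = rep("A", 40)),
               "shorter")
})

test_that("majority labels and tie-breaks follow the movement-first rule", {
  mat <- matrix(0, 48, 1)
  wd <- makeWindows(mat, 48, labels = rep(c("LR", "Null"), c(30, 18)),
                    vocabulary = c("LR", "Null"))
  expect_identical(wd@vocabulary[wd@labelIdx], "LR")
  # exact tie between a movement and Null -> the movement wins
  wd <- makeWindows(mat, 48, labels = rep(c("Null", "LR"), c(24, 24)),
                    vocabulary = c("LR", "Null"))
  expect_identical(wd@vocabulary[wd@labelIdx], "LR")
  # tie between two movements -> earliest occurrence in the window
  wd <- makeWindows(mat, 48, labels = rep(c("LL", "LR"), c(24, 24)),
                    vocabulary = c("LL", "LR", "Null"))
  expect_identical(wd@vocabulary[wd@labelIdx], "LL")
  # every window label occurs among its frame labels (property)
  set.seed(4)
  labs <- sample(c("A", "B", "Null"), 200, replace = TRUE)
  wd <- makeWindows(matrix(0, 200, 1), 24, labels = labs,
                    vocabulary = c("A", "B", "Null"))
  for (w in seq_along(wd@starts)) {
    inWin <- labs[wd@starts[w]:(wd@starts[w] + 23)]
    expect_true(wd@vocabulary[wd@labelIdx[w]] %in% inWin)
  }
})
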