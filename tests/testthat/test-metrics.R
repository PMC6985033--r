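test_that("frame fusion averages overlapping windows and fills gaps", {
  # one window covering everything: every frame gets its argmax
  f <- frameFusion(matrix(c(0.7, 0.3), 1), 1L, 10L, 10L)
  expect_identical(f$classIdx, rep(1L, 10))
  # two overlapping windows: shared frames average to (0.4, 0.6)
  probs <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  f <- frameFusion(probs, c(1L, 3L), 4L, 6L)
  expect_equal(f$probs[3, ], c(0.4, 0.6))
  expect_identical(f$classIdx[3], 2L)
  expect_equal(f$probs[1, ], c(0.6, 0.4))
  # trailing uncovered frames copy the last covered distribution
  f <- frameFusion(probs, c(1L, 3L), 4L, 16L)
  expect_equal(f$probs[16, ], f$probs[6, ])
  # probabilities remain a distribution per frame
  expect_equal(rowSums(f$probs), rep(1, 16))
  # argmax ties resolve to the lowest class index
  f <- frameFusion(matrix(c(0.5, 0.5), 1), 1L, 4L, 4L)
  expect_identical(f$classIdx, rep(1L, 4))
  expect_error(frameFusion(probs[0, , drop = FALSE], integer(), 4L, 6L),
               "no windows")
})

test_that("confusion matrices count frames exactly", {
  vocab <- c("A", "B", "Null")
  m <- confusionMatrix(c("A", "A", "B"), c("A", "A", "B"), vocab)
  expect_identical(diag(m), c(A = 2L, B = 1L, Null = 0L))
  expect_identical(sum(m) - sum(diag(m)), 0L)
  # total misclassification of one class lands in a single off-diagonal cell
  m <- confusionMatrix(rep("A", 5), rep("B", 5), vocab)
  expect_identical(m["A", "B"], 5L)
  r <- precisionRecallF1(m + 0L)
  expect_equal(unname(reportConfusion(r, percent = TRUE)["A", "B"]), 100)
  # conservation on random label vectors
  set.seed(8)
  tr <- sample(vocab, 137, replace = TRUE)
  pr <- sample(vocab, 137, replace = TRUE)
  expect_identical(sum(confusionMatrix(tr, pr, vocab)), 137L)
  expect_error(confusionMatrix(c("A", "Z"), c("A", "A"), vocab), "vocabulary")
})

test_that("precision/recall/F1 match hand-computed values", {
  # perfect prediction: everything 1
  r <- precisionRecallF1(diag(c(5L, 9L, 2L)))
  expect_equal(unname(r@micro), c(1, 1, 1))
  expect_equal(unname(r@macro), c(1, 1, 1))
  # worked 2-class example
  m <- matrix(c(8L, 3L, 2L, 7L), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  r <- precisionRecallF1(m)
  expect_equal(unname(r@micro["f1"]), 0.75)      # = accuracy 15/20
  expect_equal(r@perClass$precision[1], 8 / 11)
  expect_equal(r@perClass$recall[1], 0.8)
  # 0/0 conventions: class never predicted and never present
  m0 <- matrix(c(4L, 0L, 0L, 0L), 2)
  r0 <- precisionRecallF1(m0)
  expect_identical(r0@perClass$f1[2], 0)
  expect_error(precisionRecallF1(matrix(0L, 2, 2)), "empty")
})

test_that("micro-F1 equals accuracy, micro-precision and micro-recall", {
  set.seed(123)
  for (i in 1:1000) {
    k <- sample(2:14, 1)
    m <- matrix(rpois(k * k, 3), k)
    if (sum(m) == 0) m[1, 1] <- 1
    r <- precisionRecallF1(m)
    acc <- sum(diag(m)) / sum(m)
    expect_identical(unname(r@micro["f1"]), acc)
    expect_identical(unname(r@micro["precision"]), acc)
    expect_identical(unname(r@micro["recall"]), acc)
  }
})

test_that("mirror confusion rate counts only within-pair errors", {
  vocab <- c("XR", "XL", "SQ", "Null")
  m <- matrix(0L, 4, 4, dimnames = list(vocab, vocab))
  m["XR", "XL"] <- 30; m["XR", "XR"] <- 70
  m["XL", "XL"] <- 90; m["XL", "SQ"] <- 10
  m["SQ", "SQ"] <- 50; m["Null", "Null"] <- 50
  r <- precisionRecallF1(m)
  expect_equal(mirrorConfusionRate(r), 30 / 200)
})
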