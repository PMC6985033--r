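# Independent oracles and shared fixtures for the test suite.

# Horn's closed-form absolute-orientation solution via the eigendecomposition
# of the 4x4 quaternion profile matrix -- an independent check on the
# SVD-based rigid fit.
hornPose <- function(observed, reference) {
  co <- colMeans(observed); cr <- colMeans(reference)
  A <- sweep(reference, 2, cr)   # from
  Bm <- sweep(observed, 2, co)   # to
  M <- crossprod(A, Bm)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  t <- co - as.vector(R %*% cr)
  list(rotation = R, translation = t,
       rss = sum((sweep(reference, 2, cr) %*% t(R) -
                  sweep(observed, 2, co))^2))
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# a tiny feasible model configuration for fast network tests
tinyModelConfig <- function(nClasses = 3L, inputChannels = 3L) {
  modelConfig(windowFrames = 12L, inputChannels = inputChannels,
              kernelFrames = 2L, convChannels = 4L, lstmCells = 6L,
              nClasses = nClasses)
}

# a small linearly separable windowed dataset (nPerClass windows per class)
separableWindows <- function(nPerClass = 20L, nClasses = 2L, frames = 12L,
                             channels = 3L, shift = 2, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- nPerClass * nClasses
    X <- array(rnorm(n * frames * channels), c(n, frames, channels))
    y <- rep(seq_len(nClasses), each = nPerClass)
    for (k in seq_len(nClasses))
      X[y == k, , 1] <- X[y == k, , 1] + (k - 1) * shift
    new("WindowedDataset", windows = X, labelIdx = as.integer(y),
        vocabulary = sprintf("class%02d", seq_len(nClasses)),
        starts = seq(1L, by = 3L, length.out = n),
        windowFrames = as.integer(frames), strideFrames = 3L)
  })
}

# small cohort + extracted channels, cached across tests in one session
smallSimuFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- assembleCohort(4, templates = defaultTemplateSet()[c("STEPR", "STEPL")],
                               seed = 5, nullLead = 0.4, nullTail = 0.4)
      simu <- lapply(cohortTrials(cohort), extractSimuChannels)
      cache <<- list(cohort = cohort, simu = simu)
    }
    cache
  }
})
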