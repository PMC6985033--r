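test_that("rigid pose fit recovers exact and noisy transforms", {
  ref <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.15, 0), c(0.02, 0.05, 0.2))
  # identity
  fit <- fitSegmentPose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  # forced rotation + translation
  R90 <- eulerToRotation(c(0, 0, pi / 2))
  obs <- sweep(ref %*% t(R90), 2, c(1, 0, 0), "+")
  fit <- fitSegmentPose(obs, ref)
  expect_equal(fit$rotation, R90, tolerance = 1e-12)
  expect_equal(fit$translation, c(1, 0, 0), tolerance = 1e-12)
  expect_lt(fit$rmse, 1e-12)
  # noisy fit matches Horn's quaternion solution to 1e-10
  set.seed(31)
  for (i in 1:5) {
    R <- randomRotation()
    obs <- sweep(ref %*% t(R), 2, rnorm(3), "+") +
      matrix(rnorm(12, sd = 0.001), 4)
    fit <- fitSegmentPose(obs, ref)
    horn <- hornPose(obs, ref)
    rssFit <- sum((sweep(ref, 2, colMeans(ref)) %*% t(fit$rotation) -
                   sweep(obs, 2, colMeans(obs)))^2)
    expect_lt(abs(rssFit - horn$rss), 1e-10)
    expect_equal(fit$rotation, horn$rotation, tolerance = 1e-6)
  }
})

test_that("degenerate marker clouds are rejected", {
  line <- cbind(seq(0, 0.3, length.out = 4), 0, 0)
  expect_error(fitSegmentPose(line + 0.01, line), "collinear|degenerate")
  expect_error(fitSegmentPose(line[1:2, ], line[1:2, ]), "3 markers")
})

test_that("Euler decomposition round-trips and handles gimbal lock", {
  expect_equal(as.numeric(rotationToEuler(diag(3))), c(0, 0, 0))
  expect_equal(as.numeric(rotationToEuler(eulerToRotation(c(pi / 6, 0, 0)))),
               c(pi / 6, 0, 0), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    R <- randomRotation()
    ang <- rotationToEuler(R)
    expect_lt(max(abs(eulerToRotation(as.numeric(ang)) - R)), 1e-9)
  }
  lock <- eulerToRotation(c(0.4, pi / 2, 0)) # cos(b) = 0
  angL <- rotationToEuler(lock)
  expect_true(attr(angL, "gimbal"))
  expect_identical(angL[3], 0)
  expect_lt(max(abs(eulerToRotation(as.numeric(angL)) - lock)), 1e-8)
})

test_that("angular velocity matches closed forms", {
  fs <- 120
  n <- 121
  # constant spin about the vertical axis at 2 rad/s
  rots <- lapply(seq_len(n), function(t)
    eulerToRotation(c(0, 0, 2 * (t - 1) / fs)))
  om <- angularVelocitySeries(rots, fs)
  nrm <- sqrt(rowSums(om^2))
  expect_equal(nrm[2:(n - 1)], rep(2, n - 2), tolerance = 1e-4)
  expect_equal(om[60, ], c(0, 0, 2), tolerance = 1e-3)
  # static series -> exactly zero
  still <- angularVelocitySeries(rep(list(eulerToRotation(c(0.3, 0.2, 0.1))), 5),
                                 fs)
  expect_identical(max(abs(still)), 0)
  # time-varying axis: R(t) = Rx(sin t) has omega = (cos t, 0, 0)
  tt <- (seq_len(n) - 1) / fs
  rots <- lapply(tt, function(t) eulerToRotation(c(sin(t), 0, 0)))
  om <- angularVelocitySeries(rots, fs)
  err <- abs(om[2:(n - 1), 1] - cos(tt[2:(n - 1)]))
  # central differences: error <= ||R'''|| h^2 / 6 with
  # ||R'''|| <= |th'''| + 3|th' th''| + |th'|^3 <= 2 for th = sin(t)
  expect_lt(max(err), 2 / 6 * (1 / fs)^2 + 1e-10)
  expect_error(angularVelocitySeries(rots[1:2], fs), "3 frames")
})

test_that("COM acceleration matches constant and sinusoidal curvature", {
  fs <- 120
  tt <- (0:239) / fs
  # linear path: zero acceleration in the interior
  lin <- cbind(tt, 2 * tt, -tt)
  expect_lt(max(abs(comAccelerationSeries(lin, fs))), 1e-9)
  # free-fall parabola: ||a|| = 9.81
  par <- cbind(0 * tt, 0 * tt, -4.905 * tt^2)
  a <- comAccelerationSeries(par, fs)
  expect_equal(sqrt(rowSums(a^2)), rep(9.81, length(tt)), tolerance = 1e-6)
  # sinusoid amplitude A, frequency f: peak ||a|| ~ A (2 pi f)^2
  A <- 0.05; f <- 3
  sine <- cbind(A * sin(2 * pi * f * tt), 0 * tt, 0 * tt)
  a <- comAccelerationSeries(sine, fs)
  peak <- max(abs(a[, 1]))
  expect_equal(peak, A * (2 * pi * f)^2, tolerance = 0.01)
  expect_error(comAccelerationSeries(lin[1:2, ], fs), "3 frames")
})
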