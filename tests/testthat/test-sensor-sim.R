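tpl <- defaultTemplateSet()

test_that("sIMU extraction yields 5 channels per segment with labels intact", {
  tr <- synthesizeTrial(tpl$SQUAT, seed = 11, noiseSd = 0.001)
  s <- extractSimuChannels(tr)
  expect_s4_class(s, "SimulatedIMUSeries")
  expect_identical(nrow(s), 65L)          # 5 x 13 segments
  expect_identical(nFrames(s), nFrames(tr))
  expect_identical(frameLabels(s), frameLabels(tr))
  expect_identical(samplingRate(s), 120)
  v <- channelValues(s)
  expect_true(all(v[, grepl("norm", colnames(v))] >= 0))
})

test_that("a motionless noise-free trial has silent norm channels", {
  stat <- movementTemplate("STAT", "bilateral", 1, tpl$SQUAT@pulses[0, ])
  s <- extractSimuChannels(synthesizeTrial(stat, seed = 1, noiseSd = 0))
  v <- channelValues(s)
  expect_lt(max(abs(v[, grepl("norm", colnames(v))])), 1e-6)
})

test_that("norm channels are invariant to a fixed global rotation", {
  tr <- synthesizeTrial(tpl$LUNGR, seed = 8, noiseSd = 0)
  R <- eulerToRotation(c(0.3, -0.4, 1.2))
  co <- markerCoords(tr)
  rot <- co
  for (f in seq_len(dim(co)[1])) rot[f, , ] <- co[f, , ] %*% t(R)
  tr2 <- new("MarkerTrial", athleteId = "x", coords = rot, fs = 120,
             frameLabels = frameLabels(tr))
  v1 <- channelValues(extractSimuChannels(tr))
  v2 <- channelValues(extractSimuChannels(tr2))
  nc <- grepl("norm", colnames(v1))
  expect_lt(max(abs(v1[, nc] - v2[, nc])), 1e-8)
})

test_that("sensor configurations select the right segments", {
  tr <- synthesizeTrial(tpl$STEPR, seed = 2, noiseSd = 0.001)
  s <- extractSimuChannels(tr)
  s3l <- selectSensorConfig(s, "sIMU3L")
  expect_identical(nrow(s3l), 15L)
  expect_setequal(unique(SummarizedExperiment::rowData(s3l)$segment),
                  c("torso", "shank_L", "shank_R"))
  expect_identical(nrow(selectSensorConfig(s, "sIMU1")), 5L)
  expect_identical(nrow(selectSensorConfig(s, "sIMU13")), 65L)
  expect_error(selectSensorConfig(s, "sIMU99"), "sIMU1")
})

test_that("missing markers are reported by name and segment", {
  tr <- synthesizeTrial(tpl$STEPR, seed = 2)
  co <- markerCoords(tr)[, 1:40, ]
  tr2 <- new("MarkerTrial", athleteId = "x", coords = co, fs = 120,
             frameLabels = frameLabels(tr))
  expect_error(extractSimuChannels(tr2), "missing")
})

test_that("optical channel view flattens 45 markers to 135 columns", {
  tr <- synthesizeTrial(tpl$STEPR, seed = 2)
  opt <- opticalChannels(tr)
  expect_identical(nrow(opt), 135L)
  v <- channelValues(opt)
  expect_identical(unname(v[10, "TORSO_C7.z"]),
                   unname(markerCoords(tr)[10, "TORSO_C7", 3]))
})
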