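tpl <- defaultTemplateSet()

test_that("trial synthesis is deterministic and counts frames correctly", {
  t2 <- movementTemplate("MOVE", "bilateral", 2, tpl$SQUAT@pulses)
  a <- synthesizeTrial(t2, noiseSd = 0.001, nullLead = 0.5, nullTail = 0.5,
                       seed = 9)
  b <- synthesizeTrial(t2, noiseSd = 0.001, nullLead = 0.5, nullTail = 0.5,
                       seed = 9)
  expect_identical(markerCoords(a), markerCoords(b))
  expect_identical(nFrames(a), 360L)  # 0.5 + 2 + 0.5 s at 120 Hz
  expect_identical(sum(frameLabels(a) == "MOVE"), 240L)
  expect_identical(which(frameLabels(a) == "Null"),
                   c(1:60, 301:360))
})

test_that("a static template with no noise yields identical frames", {
  stat <- movementTemplate("STAT", "bilateral", 1, tpl$SQUAT@pulses[0, ])
  tr <- synthesizeTrial(stat, noiseSd = 0, seed = 2)
  co <- markerCoords(tr)
  for (f in c(2, 50, nFrames(tr)))
    expect_identical(co[f, , ], co[1, , ])
})

test_that("segments are rigid in noise-free trials", {
  tr <- synthesizeTrial(tpl$LUNGR, seed = 4, noiseSd = 0)
  model <- buildDefaultBodyModel()
  co <- markerCoords(tr)
  for (seg in c("shank_R", "torso", "foot_L")) {
    mk <- rownames(MotionScreen:::segmentLocalMarkers(model, seg))
    for (i in 1:(length(mk) - 1)) {
      d <- sqrt(rowSums((co[, mk[i], ] - co[, mk[i + 1], ])^2))
      expect_lt(max(d) - min(d), 1e-9)
    }
  }
})

test_that("mirrored templates generate exactly mirrored marker clouds", {
  model <- buildDefaultBodyModel()
  map <- mirrorMarkerMap(model)
  for (lab in c("STEPR", "HOPR")) {
    a <- markerCoords(synthesizeTrial(tpl[[lab]], seed = 3, noiseSd = 0))
    b <- markerCoords(synthesizeTrial(mirrorTemplate(tpl[[lab]]), seed = 3,
                                      noiseSd = 0))
    bperm <- b[, map[dimnames(a)[[2]]], ]
    bperm[, , 1] <- -bperm[, , 1]
    dimnames(bperm) <- dimnames(a)
    expect_identical(a, bperm)
  }
})

test_that("cohort assembly is a deterministic athlete x template product", {
  two <- tpl[c("STEPR", "SQUAT")]
  co1 <- assembleCohort(6, two, seed = 21)
  co2 <- assembleCohort(6, two, seed = 21)
  expect_length(cohortTrials(co1), 12L)
  expect_length(cohortAthletes(co1), 6L)
  expect_identical(labelVocabulary(co1), c("STEPR", "SQUAT", "Null"))
  expect_identical(lapply(cohortTrials(co1), markerCoords),
                   lapply(cohortTrials(co2), markerCoords))
  # athlete jitter makes trials of the same template differ
  tr <- cohortTrials(co1)
  sameTpl <- tr[vapply(tr, function(x) "STEPR" %in% frameLabels(x), NA)]
  expect_gt(max(abs(markerCoords(sameTpl[[1]])[1:100, , ] -
                    markerCoords(sameTpl[[2]])[1:100, , ])), 1e-4)
})

test_that("non-finite jitter parameters are rejected", {
  expect_error(synthesizeTrial(tpl$SQUAT,
                               athleteParams = list(amplitudeScale = NaN)),
               "finite")
})
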