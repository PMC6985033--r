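test_that("mirroring is an involution and swaps paired movement codes", {
  tpl <- defaultTemplateSet()
  for (t in tpl[c("STEPR", "LUNGR", "HOPR")]) {
    back <- mirrorTemplate(mirrorTemplate(t))
    expect_identical(back@label, t@label)
    expect_identical(back@side, t@side)
    expect_identical(back@pulses, t@pulses)  # bit-identical profiles
  }
  sdr <- movementTemplate("SDR", "right", 2,
                          data.frame(joint = "shank_R", axis = "x",
                                     amplitude = 1, center = 0.5, width = 0.8))
  expect_identical(mirrorTemplate(sdr)@label, "SDL")
  expect_error(mirrorTemplate(tpl$SQUAT), "bilateral")
})

test_that("a right-knee pulse mirrors onto the left knee only", {
  t <- movementTemplate("KNEER", "right", 2,
                        data.frame(joint = "shank_R", axis = "x",
                                   amplitude = 1.1, center = 0.5, width = 0.6))
  m <- mirrorTemplate(t)
  expect_identical(m@pulses$joint, "shank_L")
  expect_identical(m@pulses$amplitude, 1.1)  # lateral-axis rotation preserved
  # anterior/vertical rotations and lateral translations change sign
  t2 <- movementTemplate("TWISTR", "right", 2,
                         data.frame(joint = c("torso", "root"),
                                    axis = c("z", "tx"),
                                    amplitude = c(0.5, 0.3),
                                    center = 0.5, width = 0.6))
  expect_identical(mirrorTemplate(t2)@pulses$amplitude, c(-0.5, -0.3))
})

test_that("pulse profiles are smooth, plateaued and vanish at the phase edges", {
  phi <- seq(0, 1, length.out = 1001)
  y <- MotionScreen:::smoothPulse(phi, 2, 0.5, 0.8)
  expect_equal(y[1], 0)
  expect_equal(y[1001], 0)
  expect_identical(max(y), 2)              # plateau holds the amplitude
  expect_gt(mean(abs(y) > 1.99), 0.3)      # ... over a sustained span
  # second differences stay bounded (twice differentiable profile):
  # |f''| <= amp * max|s''| / (edge*width)^2, max|s''| = 5.7735 for
  # the smootherstep ramp
  d2 <- diff(y, differences = 2) / diff(phi)[1]^2
  expect_lt(max(abs(d2)), 2 * 5.7735 / (0.3 * 0.8)^2 * 1.01)
})
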