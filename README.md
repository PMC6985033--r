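# MotionScreen

Automatic recognition of athletic movement-screen tasks (squats, lunges,
hops, balance tasks) from motion data, and a study of **which body segments
need to carry a sensor** for that recognition to work.

Movement screens are scored by watching an athlete perform a battery of
standardized tasks. Data-driven scoring needs each task located inside a
continuous recording first. MotionScreen labels every frame of a
multichannel motion time series with the task being performed, using:

* a **synthetic motion-capture cohort generator** — a 13-segment,
  45-marker articulated body model performing 8 movement classes (three
  exact left/right mirror pairs + two bilateral tasks) plus a "Null"
  standing class, with athlete-to-athlete amplitude/timing jitter, postural
  sway and marker noise;
* **simulated IMU (sIMU) channels** derived from the marker trajectories:
  per segment, 3 global Euler angles plus the Euclidean norms of angular
  velocity ‖ω‖ and centre-of-mass linear acceleration ‖a‖ (norms make the
  channels independent of sensor axis alignment), low-pass filtered at
  15 Hz with a zero-lag 2nd-order Butterworth filter;
* a **ConvLSTM window classifier**: sliding windows (stride = window/4,
  majority labels) feed 4 valid temporal convolutions (ReLU) → 2 stacked
  LSTM layers → linear layer → softmax, trained by mini-batch SGD with
  momentum (batch 100) on the cross-entropy, selected by validation
  micro-averaged F1;
* **frame fusion**: every frame takes the average of the class
  probabilities of all windows containing it; reports give the frame-level
  confusion matrix and per-class/micro/macro precision, recall and F1
  (micro-F1 ≡ accuracy in this single-label setting);
* a **sensor-placement ablation** over body-segment combinations
  (`sIMU1` = torso only … `sIMU3L` = torso+shanks, `sIMU3U` =
  torso+upper-arms … `sIMU13` = all segments), retraining from scratch per
  configuration.

## Worked example

```r
library(MotionScreen)

# a small cohort: 6 athletes x 8 movements at 120 Hz
cohort <- assembleCohort(nAthletes = 6, seed = 1)
cohort
#> MotionCohort: 48 trials, 6 athletes, classes: STEPR, STEPL, LUNGR, LUNGL,
#>   HOPR, HOPL, SQUAT, JUMP, Null

# simulated IMU channels for one trial: 5 channels x 13 segments
simu <- extractSimuChannels(cohortTrials(cohort)[[1]])
simu
#> class: SimulatedIMUSeries
#> dim: 65 291
#> rownames(65): pelvis.euler_x pelvis.euler_y ... foot_R.gyro_norm
#>   foot_R.accel_norm
#> colData names(1): label

# torso + shanks sensor set
nrow(selectSensorConfig(simu, "sIMU3L"))
#> [1] 15

# athlete-level split (matches 278/69/70 at n = 417)
lengths(splitAthletes(sprintf("A%03d", 1:417), seed = 1))
#>      train validation       test
#>        278         69         70
```

A full experiment — generate, extract, split, normalize, window, train,
evaluate frame-by-frame — runs from one declarative config:

```r
res <- runExperiment(list(
  cohort = list(nAthletes = 12, seed = 7),
  input  = list(mode = "sIMU", config = "sIMU3L"),
  train  = list(learningRate = 0.015, momentum = 0.9, batchSize = 50,
                maxEpochs = 30, seed = 7)))
res$report
#> EvaluationReport: 4776 frames, micro-F1 0.8342, macro-F1 0.8035
round(reportConfusion(res$report, percent = TRUE))[1:4, 1:5]
#>       STEPR STEPL LUNGR LUNGL HOPR
#> STEPR    62     0     0     0    0
#> STEPL     0    86     0     0    0
#> LUNGR     0     0    92     0    0
#> LUNGL     0     0     0    92    0
```

The frames a torso+shanks sensor set misses are mostly movement/Null
boundary frames and mirror-pair swaps; the full-body `sIMU13`
configuration recovers frame-level micro-F1 ≈ 0.94 under the same
conditions (see `scripts/acceptance.R` output).

`runSensorAblation()` repeats training/evaluation across sensor
configurations and tabulates micro/macro F1 and the left/right
mirror-confusion rate per configuration.

## Package layout

* `R/` — S4 classes (`MarkerTrial`, `SimulatedIMUSeries`,
  `WindowedDataset`, `ConvLSTMModel`, `EvaluationReport`, …) and the
  pipeline stages described above.
* `vignettes/movement-screen-classification.Rmd` — the model, its
  assumptions, parameter defaults, numerical choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites (closed-form
  kinematics oracles, filter response checks, metric identities,
  end-to-end recovery).
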