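---
title: "Recognizing movement-screen tasks from motion capture and simulated IMU data"
author: "MotionScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing movement-screen tasks from motion capture and simulated IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MotionScreen)
```

# The problem

Movement screens assess an athlete's movement quality from a standardized
battery of tasks (squats, lunges, hops, balance tasks). Data-driven scoring
of these screens needs to know *when* each task happens inside a continuous
motion recording. MotionScreen implements a recognition pipeline that labels
every frame of a multichannel motion recording with the task being
performed, and asks a second question of practical importance for wearable
deployment: *which body segments must carry a sensor* for recognition to
work?

The pipeline has five stages:

1. **Synthetic cohort generation** — labeled 45-marker trajectories for a
   cohort of athletes (`assembleCohort`), standing in for a private
   motion-capture dataset.
2. **Simulated IMU (sIMU) extraction** — per body segment, three global
   orientation Euler angles plus the Euclidean norms of the segment angular
   velocity and centre-of-mass linear acceleration
   (`extractSimuChannels`), with sensor subsets selected by configuration
   code (`selectSensorConfig`).
3. **Dataset construction** — athlete-level train/validation/test split
   (`splitAthletes`), channel z-normalization with training statistics only
   (`fitNormalization`), sliding windows with majority labels
   (`makeWindows`).
4. **Classification** — a convolutional-recurrent network
   (`buildModel`/`trainModel`): four valid temporal convolutions with ReLU,
   two stacked LSTM layers, a linear layer on the last LSTM step, softmax;
   trained by mini-batch SGD with momentum on the cross-entropy.
5. **Frame-level evaluation** — per-frame fusion of window probabilities
   (`frameFusion`), confusion matrices and micro/macro
   precision/recall/F1 (`precisionRecallF1`), hyperparameter grid search
   (`gridSearchLearning`, `gridSearchArchitecture`) and the
   sensor-placement ablation (`runSensorAblation`).

# The synthetic cohort: what it emulates and what it does not

The generator articulates a 13-segment rigid-body model (pelvis root,
torso, head, and left/right upper arms, forearms, thighs, shanks, feet)
carrying 45 named markers, each segment with at least three non-collinear
markers so its pose is observable. Movements are parametric templates:
smooth plateau pulses of joint angles and root translation over a
normalized phase — smootherstep ($6x^5-15x^4+10x^3$) ramps over the outer
30% of each pulse's support with the amplitude held in between — so
profiles are twice continuously differentiable, join the flanking
quiet-standing ("Null") periods with continuous accelerations, and hold a
posture recognizably different from standing for most of the labeled
movement span. (An earlier design with $\sin^4$ bumps left roughly a
quarter of the movement-labeled frames quasi-static and therefore
indistinguishable from Null; labels must mark frames whose content is
actually movement-specific for frame-level scoring to be meaningful.)

The default library (`defaultTemplateSet`) holds eight classes: three
left/right mirror pairs (step-down, forward lunge, lateral hop) and two
bilateral tasks (deep squat, countermovement jump), plus Null. Mirror
pairs are exact sagittal reflections (`mirrorTemplate` is an involution and
the generated marker clouds mirror bit-exactly). By construction the
central segments rotate only about the lateral axis and the arms move
bilaterally symmetrically, so *torso and upper-arm channels are identical
between the two members of a mirror pair*: chirality lives in the lower
limbs. This reproduces the structural reason a torso- or arm-only sensor
set confuses left and right task versions while a torso+shanks set does
not.

Defaults (chosen once, as plausible for an athletic screening session, and
used by the test suite and the acceptance script): 120 Hz sampling; 1.6 s
movements with 0.4 s Null lead-in/out; athlete-to-athlete amplitude jitter
12% and timing jitter 8% (plus 3% trial-to-trial amplitude jitter);
isotropic marker noise 2 mm; postural sway up to 4 mm of smooth
low-frequency root motion. All randomness flows through one seed per call;
identical seeds give bit-identical cohorts.

Not emulated: soft-tissue artefact, marker occlusion/dropout, ground
reaction forces, inter-movement transitions (each trial is one movement),
and real IMU error sources (bias drift, misalignment). Passing tests on
this cohort therefore demonstrate the pipeline's correctness and the
structural sensor-placement effects, not field performance on real
athletes.

# Simulated IMU channels and the processing chain

For each segment, per frame, the rigid pose is recovered from the
segment's markers by the least-squares (SVD/Kabsch) fit with reflection
exclusion (`fitSegmentPose`); an independent quaternion-based solution is
used as a test oracle. Orientation is reported as Cardan x-y-z Euler
angles (`rotationToEuler`; at gimbal lock the third angle is set to zero
and the frame flagged). Angular velocity comes from the skew part of
$\dot R R^\top$ with central differences; linear acceleration is the second
central difference of the marker-centroid path (the segment centre-of-mass
proxy).

The processing chain applies the 15 Hz zero-lag second-order Butterworth
filter (`zeroLagButterworth`, forward-backward, odd-reflection padding of
$3(\mathrm{order}+1)$ samples, DC-exact) at three points:

1. marker trajectories, before pose estimation;
2. the angular-velocity and acceleration *components*, before the norms;
3. the norm channels themselves.

Points 1-2 matter numerically: differentiation amplifies marker noise
toward the Nyquist frequency, and once a norm is taken, noise becomes a
*positive bias* of the norm that no later filter can remove (with 2 mm
marker noise the bias reaches several rad/s — larger than the movement
signal). Filtering before the nonlinearity is the standard
motion-capture practice; because filtering is linear and norms are
rotation-invariant, the norm channels remain exactly invariant to a fixed
global rotation of the laboratory frame — the property that motivates
using norms instead of vector components in the first place (no dependence
on sensor alignment). Euler angle channels are left unfiltered beyond the
trajectory smoothing.

Each segment contributes exactly 5 channels; the optical input mode
(`opticalChannels`) instead uses the 3 x 45 = 135 raw coordinate channels.
Sensor configurations (`sensorConfigTable`) range from a single torso
sensor (`sIMU1`, 5 channels) through torso+shanks (`sIMU3L`) and
torso+upper-arms (`sIMU3U`) to all thirteen segments (`sIMU13`, 65
channels).

# Dataset construction

Athletes (never trials) are split 2/3 train, with the remainder halved
into validation (floor) and test (ceiling) — 417 athletes give 278/69/70.
Channel means and standard deviations are computed on the pooled training
frames only (constant channels have their sd floored so they normalize to
zero) and reused unchanged for validation and test; they are refit for
every sensor configuration, since each configuration is an independent
experiment.

Windows of SWS frames advance by SWS/4; trailing frames that do not fill a
window are dropped at training time (frame fusion restores full coverage at
test time). A window takes the label of the class occupying the majority
of its frames; ties prefer a movement class over Null, then the earliest
label in the window. The deliberate consequence is that windows straddling
a movement/Null boundary carry noisy labels — the main irreducible error
source at frame level, visible as start/end smearing of predicted
segments.

# The classifier

The network follows the established deep convolutional-LSTM design for
wearable activity recognition: four *valid* (unpadded) temporal
convolutions (kernel $k$ frames, $C$ feature maps, ReLU) slide over the
SWS x N window; the resulting per-step feature vectors feed two stacked
LSTM layers of $L$ cells; the last step's hidden state passes through one
linear layer and a softmax over the classes. A window of SWS frames keeps
$SWS - 4(k-1)$ steps after the convolutions (`convOutputLength`), which
must be positive for a configuration to be feasible.

Implementation choices fixed where the source architecture leaves detail
open: no pooling, no padding, dropout (inverted, on the last LSTM output)
off by default, classification from the last time step. Initialization is
uniform with fan-in scaling; convolution biases start non-negative so no
ReLU stack begins dead, and LSTM forget-gate biases start at +1 — without
the latter, gradient flow through the two recurrent layers is too weak for
plain SGD to escape the class-prior plateau at desk scale. Training is
mini-batch SGD with momentum (batch 100 by default) on the cross-entropy;
the best-validation-epoch parameters are retained with early stopping
(window-level micro-F1, the same metric used for model selection in the
grid searches). Everything — initialization, shuffling, dropout — is
driven by one seed, and the whole forward/backward pass is plain BLAS
matrix algebra, so runs are exactly reproducible.

The two-stage hyperparameter search mirrors standard practice: learning
rate and momentum first (5 x 5 grid), then window/kernel/channels/cells
(kernels 5-6 with 24-frame windows and 6-8 with 48-frame windows; 36
combinations), selecting by validation window-level micro-F1. Stage-2 ties
prefer the smaller model.

# Frame-level evaluation

At test time the classifier runs per athlete: all trials are concatenated,
windowed, classified, and every frame receives the arithmetic mean of the
probability vectors of all windows containing it; the argmax (ties to the
lowest class index) is the frame's label, and frames not covered by any
window inherit the nearest covered frame's distribution. Reports contain
the frame-level confusion matrix and per-class/micro/macro precision,
recall and F1. Micro-averaged F1 equals micro precision, micro recall and
accuracy in this single-label setting — an identity the test suite checks
exactly on a thousand random confusion matrices. Per-athlete confusion
matrices are summed for subset-level reports, so the aggregate micro-F1 is
the pooled frame accuracy.

`mirrorConfusionRate` summarizes chirality errors: the fraction of frames
of mirror-pair classes predicted as the *other* member of the same pair.

# Desk-scale study conditions

The package's end-to-end experiments (test suite and acceptance script)
run on one CPU in minutes, so the cohort is deliberately smaller than a
laboratory study while keeping every structural property: 8 movement
classes + Null, one trial per movement and athlete, 24 athletes (16/4/4
athlete-level split) in the single-seed acceptance-script run and 16
athletes (10/3/3) in the triplicated test-suite replicates. The network
uses the reference architecture (SWS 48, kernel 6, C = 32 convolution
channels, L = 64 LSTM cells); mini-batches of 50 with learning rate 0.015
and momentum 0.9 were selected by validation micro-F1 on this desk-scale
problem — the same validation-driven selection the full two-stage grid
search implements (at ~500x less data than a laboratory study, the
optimal learning parameters differ from a full-size study's). Under these
conditions the full-body sIMU13 configuration reaches frame-level
micro-F1 >= 0.85 with margin, the torso-only configuration is markedly
worse, and sensor sets without lower limbs show a much higher left/right
mirror-confusion rate — the qualitative sensor-placement findings the
ablation is designed to expose.

# Numerical notes and limitations

* **Rigid fit**: residuals on noise-free rigid data are < 1e-10 m; the
  reflection case (det = -1) is excluded by construction. Collinear
  reference clouds are rejected.
* **Gimbal lock**: |cos b| < 1e-8 triggers the documented convention
  (third angle zero, frame flagged).
* **Filter edges**: odd-reflection padding with DC-exact initial state;
  constant series pass through bit-near-exactly; the zero-phase property
  holds to < 1e-9 for centred impulses.
* **Determinism**: results are reproducible to the bit for a fixed seed on
  a given BLAS; across BLAS implementations small last-digit differences
  can occur.
* **Class imbalance**: Null frames are a minority by design (trials are
  mostly movement); no rebalancing is applied.
* **Known limitation**: movement/Null boundary frames are the dominant
  error mode (window labels and fused probabilities are both ambiguous
  there); post-hoc smoothing of the frame sequence would likely help but
  is out of scope.
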