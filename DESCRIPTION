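Package: MotionScreen
Title: Recognition of Athletic Movement-Screen Tasks from Motion Capture
    and Simulated Wearable-Sensor Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic recognition of athletic movement-screen
    tasks from optical motion-capture data and from simulated inertial
    measurement unit (sIMU) channels derived from marker trajectories.
    Provides a synthetic labeled motion-capture cohort generator (13 rigid
    body segments, 45 markers, mirror-image movement pairs, null periods),
    rigid-body pose estimation and sIMU channel extraction (global Euler
    angles, angular-velocity and linear-acceleration norms, zero-lag
    Butterworth filtering), athlete-level train/validation/test splitting,
    sliding-window datasets with majority labels, a convolutional-recurrent
    (ConvLSTM) window classifier trained by stochastic gradient descent with
    momentum, per-frame fusion of window probabilities, micro/macro
    precision-recall-F1 evaluation, two-stage hyperparameter grid search,
    and a body-segment sensor-placement ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MotionScreen-package.R'
    'RcppExports.R'
    'bodyModel.R'
    'filter.R'
    'kinematics.R'
    'sensorSim.R'
    'windowing.R'
    'templates.R'
    'synthesize.R'
    'nnCore.R'
    'convlstm.R'
    'metrics.R'
    'evaluate.R'
    'io.R'
    'methods.R'
    'tuning.R'
    'pipeline.R'
    'plots.R'
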