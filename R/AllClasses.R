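#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Articulated 13-segment, 45-marker body model
#'
#' Describes the rigid-body marker model used both to synthesize marker
#' trajectories (forward kinematics) and to recover segment poses from
#' observed markers.  The model has 13 segments (head, torso, pelvis and
#' left/right upper arms, forearms, thighs, shanks, feet) carrying 45 named
#' markers in total; every segment carries at least three non-collinear
#' markers so that its pose is observable.
#'
#' @slot markers data.frame with columns \code{marker}, \code{segment},
#'   \code{x}, \code{y}, \code{z}: marker local coordinates (m) in the
#'   segment frame. Coordinate convention: x lateral (+ left), y anterior,
#'   z up.
#' @slot segments data.frame with columns \code{segment}, \code{parent}
#'   (\code{NA} for the root), \code{ox}, \code{oy}, \code{oz}: the joint
#'   centre of each segment expressed in its parent's frame (m); for the
#'   root, in the global frame.
#' @export
setClass("BodyModel",
  representation(markers = "data.frame", segments = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@segments) != 13L)
      msg <- c(msg, "model must have exactly 13 segments")
    if (nrow(object@markers) != 45L)
      msg <- c(msg, "model must have exactly 45 markers")
    if (anyDuplicated(object@markers$marker))
      msg <- c(msg, "marker names must be unique")
    if (!all(object@markers$segment %in% object@segments$segment))
      msg <- c(msg, "every marker must belong to a known segment")
    for (seg in object@segments$segment) {
      loc <- as.matrix(object@markers[object@markers$segment == seg,
                                      c("x", "y", "z")])
      if (nrow(loc) < 3L) {
        msg <- c(msg, sprintf("segment '%s' carries fewer than 3 markers", seg))
      } else {
        sv <- svd(scale(loc, scale = FALSE))$d
        if (sv[2] < 1e-8)
          msg <- c(msg, sprintf("markers of segment '%s' are collinear", seg))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Parametric movement template
#'
#' A movement is described as a set of smooth joint-angle and root-translation
#' pulses over a normalized phase \eqn{\phi \in [0, 1]}.  Each pulse is a
#' plateau bump with smootherstep ramps: twice continuously differentiable,
#' vanishing with its derivatives at the support edges (so accelerations
#' exist and trials join null periods smoothly), and holding its peak over
#' the middle of the support so the labeled movement posture stays distinct
#' from quiet standing.
#'
#' @slot label Movement class code (e.g. \code{"SDR"}, or a synthetic code).
#' @slot side \code{"left"}, \code{"right"} or \code{"bilateral"}.
#' @slot duration Nominal movement duration in seconds.
#' @slot pulses data.frame with columns \code{joint} (segment name whose
#'   joint rotates, or \code{"root"} for translation), \code{axis}
#'   (\code{"x"},\code{"y"},\code{"z"} for rotation in rad, or
#'   \code{"tx"},\code{"ty"},\code{"tz"} for translation in m),
#'   \code{amplitude}, \code{center}, \code{width} (phase units).
#' @export
setClass("MovementTemplate",
  representation(label = "character", side = "character",
                 duration = "numeric", pulses = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@side %in% c("left", "right", "bilateral"))
      msg <- c(msg, "side must be left, right or bilateral")
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    need <- c("joint", "axis", "amplitude", "center", "width")
    if (!all(need %in% names(object@pulses)))
      msg <- c(msg, "pulses must have columns joint, axis, amplitude, center, width")
    else {
      if (!all(object@pulses$axis %in% c("x", "y", "z", "tx", "ty", "tz")))
        msg <- c(msg, "pulse axis must be one of x,y,z,tx,ty,tz")
      bad <- object@pulses$center - object@pulses$width / 2 < -1e-12 |
             object@pulses$center + object@pulses$width / 2 > 1 + 1e-12
      if (any(bad))
        msg <- c(msg, "pulse support must lie within phase [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' One labeled marker-trajectory trial
#'
#' Marker positions for a single movement trial of a single athlete, with a
#' per-frame class label ("Null" outside the movement).
#'
#' @slot athleteId Character athlete identifier.
#' @slot coords numeric array \code{frames x markers x 3} (m), marker names
#'   in \code{dimnames[[2]]}.
#' @slot fs Sampling rate (Hz); 120 by default throughout the package.
#' @slot frameLabels Character vector, one label per frame.
#' @export
setClass("MarkerTrial",
  representation(athleteId = "character", coords = "array",
                 fs = "numeric", frameLabels = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "coords must be a frames x markers x 3 array")
    if (length(object@frameLabels) != d[1])
      msg <- c(msg, "frameLabels length must equal frame count")
    if (object@fs <= 0) msg <- c(msg, "fs must be positive")
    if (anyNA(object@coords)) msg <- c(msg, "coords must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' Labeled multichannel time series
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding a channels x
#' frames matrix in the \code{"channels"} assay, channel annotation
#' (\code{segment}, \code{type}) in \code{rowData}, per-frame labels in
#' \code{colData$label}, and \code{fs}, \code{athleteId} and trial
#' \code{boundaries} in \code{metadata}.
#'
#' @export
setClass("ChannelSeries", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"channels" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'channels' is required")
    if (!"label" %in% names(colData(object)))
      msg <- c(msg, "colData must have a 'label' column")
    if (is.null(metadata(object)$fs))
      msg <- c(msg, "metadata$fs is required")
    if (length(msg)) msg else TRUE
  })

#' Simulated-IMU channel series
#'
#' A \linkS4class{ChannelSeries} whose channels are the five simulated
#' inertial channels per body segment: three global-orientation Euler angles
#' (rad), the Euclidean norm of the segment angular velocity (rad/s) and the
#' Euclidean norm of the segment centre-of-mass linear acceleration (m/s^2).
#'
#' @export
setClass("SimulatedIMUSeries", contains = "ChannelSeries",
  validity = function(object) {
    rd <- rowData(object)
    tab <- table(rd$segment)
    if (!all(tab == 5L))
      return("each segment must contribute exactly 5 channels")
    TRUE
  })

#' Per-channel normalization statistics
#'
#' Channel-wise mean and standard deviation computed on the training frames
#' only; the standard deviation is floored at \code{epsilon} so constant
#' channels normalize to zero.
#'
#' @slot mean,sd Named numeric vectors, one entry per channel.
#' @slot epsilon Positive floor applied to \code{sd}.
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric", epsilon = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mean) != length(object@sd))
      msg <- c(msg, "mean and sd must have the same length")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (length(msg)) msg else TRUE
  })
setClassUnion("NormalizationStatsOrNULL", c("NormalizationStats", "NULL"))

#' Sliding-window dataset
#'
#' Fixed-length windows cut from a labeled channel series with stride
#' \code{strideFrames} (window/4 by default), each carrying the majority
#' frame label (ties favour a movement class over "Null", then the earliest
#' label in the window).
#'
#' @slot windows numeric array \code{n x windowFrames x channels}.
#' @slot labelIdx integer vector of 1-based indices into \code{vocabulary}.
#' @slot vocabulary character label vocabulary (movements then "Null").
#' @slot starts integer 1-based start frame of each window in the source
#'   series.
#' @slot windowFrames,strideFrames integer window geometry.
#' @export
setClass("WindowedDataset",
  representation(windows = "array", labelIdx = "integer",
                 vocabulary = "character", starts = "integer",
                 windowFrames = "integer", strideFrames = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@windows)
    if (length(d) != 3L) msg <- c(msg, "windows must be a 3-d array")
    if (d[1] != length(object@labelIdx) || d[1] != length(object@starts))
      msg <- c(msg, "labelIdx and starts must match the window count")
    if (any(object@labelIdx < 1L | object@labelIdx > length(object@vocabulary)))
      msg <- c(msg, "labelIdx out of vocabulary range")
    if (length(object@starts) > 1 &&
        any(diff(object@starts) != object@strideFrames))
      msg <- c(msg, "window starts must increase by strideFrames")
    if (length(msg)) msg else TRUE
  })

#' ConvLSTM architecture configuration
#'
#' @slot windowFrames Sliding-window size SWS (frames).
#' @slot inputChannels Number of input columns N (3 x 45 for optical marker
#'   input; 5 x number of segments for simulated IMU input).
#' @slot convLayers Number of temporal convolution layers (4).
#' @slot kernelFrames Temporal kernel size k.
#' @slot convChannels Feature maps per convolution C.
#' @slot lstmLayers Number of stacked LSTM layers (2).
#' @slot lstmCells LSTM cells L.
#' @slot nClasses Output classes (14 = 13 movements + "Null" by default).
#' @slot dropoutRate Dropout on the last LSTM output during training (0 off).
#' @export
setClass("ModelConfig",
  representation(windowFrames = "integer", inputChannels = "integer",
                 convLayers = "integer", kernelFrames = "integer",
                 convChannels = "integer", lstmLayers = "integer",
                 lstmCells = "integer", nClasses = "integer",
                 dropoutRate = "numeric"),
  validity = function(object) {
    msg <- character()
    cnt <- c(object@windowFrames, object@inputChannels, object@convLayers,
             object@kernelFrames, object@convChannels, object@lstmLayers,
             object@lstmCells, object@nClasses)
    if (any(cnt < 1L)) msg <- c(msg, "all counts must be positive")
    tOut <- object@windowFrames - object@convLayers * (object@kernelFrames - 1L)
    if (tOut < 1L)
      msg <- c(msg, sprintf(
        "infeasible config: %d frames - %d x (%d - 1) = %d < 1 after the convolutions",
        object@windowFrames, object@convLayers, object@kernelFrames, tOut))
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Optimization configuration for ConvLSTM training
#'
#' Mini-batch stochastic gradient descent with momentum on the cross-entropy
#' loss; mini-batch size 100 by default.
#'
#' @slot learningRate Positive SGD learning rate.
#' @slot momentum Momentum coefficient in [0, 1).
#' @slot batchSize Mini-batch size (default 100).
#' @slot maxEpochs Maximum training epochs.
#' @slot patience Early-stopping patience (epochs without material
#'   validation improvement); ignored when no validation set is given.
#' @slot minDelta Smallest validation micro-F1 gain counted as material
#'   improvement for the patience counter (best parameters are still
#'   retained for any improvement).
#' @slot seed Integer seed controlling initialization and batch shuffling.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", minDelta = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
    if (object@momentum < 0 || object@momentum >= 1)
      msg <- c(msg, "momentum must be in [0, 1)")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
    if (length(msg)) msg else TRUE
  })

#' A (possibly trained) ConvLSTM window classifier
#'
#' @slot params Named list of parameter matrices (convolution, LSTM, linear).
#' @slot config \linkS4class{ModelConfig}.
#' @slot vocabulary Class label vocabulary the output indices refer to.
#' @slot stats \linkS4class{NormalizationStats} used for its inputs, or NULL.
#' @slot history data.frame with one row per epoch (loss, validation F1).
#' @slot trained logical.
#' @export
setClass("ConvLSTMModel",
  representation(params = "list", config = "ModelConfig",
                 vocabulary = "character", stats = "NormalizationStatsOrNULL",
                 history = "data.frame", trained = "logical"))

#' Frame-level evaluation report
#'
#' Confusion matrix (rows = true class) plus per-class and micro/macro
#' precision, recall and F1.  For single-label multiclass data the
#' micro-averaged F1 equals the micro precision, micro recall and the
#' overall accuracy.
#'
#' @slot confusion Integer counts matrix, rows = true classes.
#' @slot perClass data.frame: class, precision, recall, f1, support.
#' @slot micro,macro Named numeric vectors (precision, recall, f1).
#' @slot nFrames Number of frames scored.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 micro = "numeric", macro = "numeric", nFrames = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@confusion < 0)) msg <- c(msg, "confusion counts must be >= 0")
    if (sum(object@confusion) != object@nFrames)
      msg <- c(msg, "confusion total must equal nFrames")
    if (length(msg)) msg else TRUE
  })

#' A synthetic multi-athlete cohort of labeled marker trials
#'
#' @slot trials List of \linkS4class{MarkerTrial} objects.
#' @slot vocabulary Movement labels present, plus "Null" (last).
#' @slot seed Seed the cohort was generated from.
#' @export
setClass("MotionCohort",
  representation(trials = "list", vocabulary = "character", seed = "integer"))
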