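#' @include AllClasses.R nnCore.R windowing.R
NULL

#' Temporal length remaining after the convolution stack
#'
#' Each valid (unpadded) temporal convolution with kernel \code{k} shortens
#' the window by \code{k - 1} frames; after \code{nLayers} layers a window
#' of \code{sws} frames keeps \code{sws - nLayers * (k - 1)} steps, which
#' must be at least 1 for the configuration to be feasible.
#'
#' @param sws Sliding-window size (frames).
#' @param k Convolution kernel size (frames).
#' @param nLayers Number of convolution layers (default 4).
#' @return Integer number of remaining time steps.
#' @export
convOutputLength <- function(sws, k, nLayers = 4L) {
  out <- as.integer(sws) - as.integer(nLayers) * (as.integer(k) - 1L)
  if (out < 1L)
    stop("infeasible configuration: window of ", sws, " frames leaves ",
         out, " steps after ", nLayers, " convolutions with kernel ", k)
  out
}

#' Construct a ConvLSTM architecture configuration
#'
#' @param windowFrames Sliding-window size SWS (frames).
#' @param inputChannels Input columns N (135 for optical input with 45
#'   markers; 5 x segments for simulated IMU input).
#' @param kernelFrames Convolution kernel size k.
#' @param convChannels Convolution feature maps C.
#' @param lstmCells LSTM cells L.
#' @param nClasses Number of classes (default 14: 13 movements + "Null").
#' @param convLayers,lstmLayers Layer counts (defaults 4 and 2).
#' @param dropoutRate Dropout rate on the final LSTM output (default 0).
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(windowFrames, inputChannels, kernelFrames = 6L,
                        convChannels = 32L, lstmCells = 64L,
                        nClasses = 14L, convLayers = 4L, lstmLayers = 2L,
                        dropoutRate = 0) {
  new("ModelConfig",
      windowFrames = as.integer(windowFrames),
      inputChannels = as.integer(inputChannels),
      convLayers = as.integer(convLayers),
      kernelFrames = as.integer(kernelFrames),
      convChannels = as.integer(convChannels),
      lstmLayers = as.integer(lstmLayers),
      lstmCells = as.integer(lstmCells),
      nClasses = as.integer(nClasses),
      dropoutRate = dropoutRate)
}

#' Construct a training configuration
#'
#' @param learningRate SGD learning rate.
#' @param momentum SGD momentum in [0, 1).
#' @param batchSize Mini-batch size (default 100).
#' @param maxEpochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param minDelta Minimum validation micro-F1 gain that counts as
#'   improvement for the patience counter (default 0.002).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.001, momentum = 0.9,
                        batchSize = 100L, maxEpochs = 100L,
                        patience = 10L, minDelta = 0.002, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), minDelta = minDelta,
      seed = as.integer(seed))
}

# uniform(-s, s) initialization, PyTorch-style fan-in scaling
.initParams <- function(cfg, seed) {
  u <- function(n, s) stats::runif(n, -s, s)
  withSeed(seed, {
    conv <- vector("list", cfg@convLayers)
    cin <- cfg@inputChannels
    for (l in seq_len(cfg@convLayers)) {
      fanIn <- cfg@kernelFrames * cin
      s <- 1 / sqrt(fanIn)
      # conv biases start nonnegative so no ReLU stack begins dead
      conv[[l]] <- list(W = matrix(u(fanIn * cfg@convChannels, s), fanIn),
                        b = stats::runif(cfg@convChannels, 0, s))
      cin <- cfg@convChannels
    }
    lstm <- vector("list", cfg@lstmLayers)
    lin <- cfg@convChannels
    for (l in seq_len(cfg@lstmLayers)) {
      s <- 1 / sqrt(cfg@lstmCells)
      b0 <- u(4L * cfg@lstmCells, s)
      # forget-gate bias starts at +1 so early cell memory persists and
      # gradients reach the convolution stack
      fgate <- (cfg@lstmCells + 1L):(2L * cfg@lstmCells)
      b0[fgate] <- b0[fgate] + 1
      lstm[[l]] <- list(
        Wx = matrix(u(lin * 4L * cfg@lstmCells, s), lin),
        Wh = matrix(u(cfg@lstmCells * 4L * cfg@lstmCells, s), cfg@lstmCells),
        b = b0)
      lin <- cfg@lstmCells
    }
    s <- 1 / sqrt(cfg@lstmCells)
    fc <- list(W = matrix(u(cfg@lstmCells * cfg@nClasses, s), cfg@lstmCells),
               b = u(cfg@nClasses, s))
    list(conv = conv, lstm = lstm, fc = fc)
  })
}

#' Build an untrained ConvLSTM window classifier
#'
#' Four valid temporal convolutions (kernel \code{k} over the time axis,
#' \code{C} feature maps, ReLU), two stacked LSTM layers of \code{L} cells,
#' a linear layer from the last time step to the class scores, and a
#' softmax.  Parameter initialization is uniform with fan-in scaling and
#' fully seeded.
#'
#' @param cfg A \linkS4class{ModelConfig}.
#' @param vocabulary Class labels (length \code{cfg@nClasses}).
#' @param seed Integer initialization seed.
#' @return An untrained \linkS4class{ConvLSTMModel}.
#' @export
buildModel <- function(cfg, vocabulary = NULL, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  if (is.null(vocabulary))
    vocabulary <- sprintf("class%02d", seq_len(cfg@nClasses))
  stopifnot(length(vocabulary) == cfg@nClasses)
  new("ConvLSTMModel", params = .initParams(cfg, seed), config = cfg,
      vocabulary = vocabulary, stats = NULL,
      history = data.frame(epoch = integer(), loss = numeric(),
                           valF1 = numeric()),
      trained = FALSE)
}

#' Number of trainable parameters of a model
#'
#' @param model A \linkS4class{ConvLSTMModel} or \linkS4class{ModelConfig}.
#' @return Integer parameter count.
#' @export
nParameters <- function(model) {
  if (is(model, "ModelConfig")) model <- buildModel(model)
  sum(unlist(.treeMap(length, model@params)))
}

# window-level accuracy (= micro-F1 at the window level)
.windowAccuracy <- function(params, cfg, X, y, batchSize = 512L) {
  n <- dim(X)[1]
  correct <- 0L
  for (s in seq.int(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    p <- .nnForward(params, X[idx, , , drop = FALSE], cfg)$probs
    correct <- correct + sum(max.col(p, ties.method = "first") == y[idx])
  }
  correct / n
}

#' Train a ConvLSTM window classifier
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy.  After each epoch the window-level micro-averaged F1
#' (equal to window accuracy) is computed on the validation windows; the
#' parameters of the best validation epoch are retained and training stops
#' early after \code{patience} epochs without improvement.  With no
#' validation set the model trains for \code{maxEpochs} and keeps the final
#' parameters.  The run is fully determined by \code{tcfg@seed}.
#'
#' @param model An untrained (or pre-trained) \linkS4class{ConvLSTMModel}.
#' @param data Training \linkS4class{WindowedDataset}.
#' @param val Validation \linkS4class{WindowedDataset} or NULL.
#' @param tcfg A \linkS4class{TrainConfig}.
#' @param stats Optional \linkS4class{NormalizationStats} to store with the
#'   model (inputs are expected already normalized).
#' @param verbose Print per-epoch progress.
#' @return The trained \linkS4class{ConvLSTMModel} with history.
#' @export
trainModel <- function(model, data, val = NULL, tcfg = trainConfig(),
                       stats = NULL, verbose = FALSE) {
  stopifnot(is(model, "ConvLSTMModel"), is(data, "WindowedDataset"))
  cfg <- model@config
  X <- data@windows
  y <- data@labelIdx
  n <- dim(X)[1]
  if (n < 1L) stop("training dataset is empty")
  if (max(y) > cfg@nClasses)
    stop("label index ", max(y), " exceeds nClasses = ", cfg@nClasses)
  if (dim(X)[3] != cfg@inputChannels)
    stop("window channel count ", dim(X)[3], " does not match model N = ",
         cfg@inputChannels)
  hasVal <- !is.null(val) && length(val@labelIdx) > 0
  params <- .deepCopy(model@params)
  velocity <- .treeMap(function(p) p * 0, params)
  bestParams <- model@params
  bestF1 <- -Inf
  patienceMark <- -Inf
  sinceBest <- 0L
  hist <- list()
  withSeed(tcfg@seed, {
    for (epoch in seq_len(tcfg@maxEpochs)) {
      perm <- sample.int(n)
      epochLoss <- 0
      for (s in seq.int(1L, n, by = tcfg@batchSize)) {
        idx <- perm[s:min(s + tcfg@batchSize - 1L, n)]
        fwd <- .nnForward(params, X[idx, , , drop = FALSE], cfg,
                          training = TRUE, keepCache = TRUE)
        loss <- .crossEntropy(fwd$probs, y[idx])
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", epoch,
               " (learning rate too high?)")
        grads <- .nnBackward(params, fwd, cfg, y[idx])
        .sgdStepInPlace(params, velocity, grads,
                        tcfg@learningRate, tcfg@momentum)
        epochLoss <- epochLoss + loss * length(idx)
      }
      epochLoss <- epochLoss / n
      valF1 <- if (hasVal)
        .windowAccuracy(params, cfg, val@windows, val@labelIdx) else NA_real_
      hist[[epoch]] <- data.frame(epoch = epoch, loss = epochLoss,
                                  valF1 = valF1)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val F1 %s", epoch, epochLoss,
                        ifelse(is.na(valF1), "-", sprintf("%.4f", valF1))))
      if (hasVal) {
        if (valF1 > bestF1) {
          bestF1 <- valF1
          bestParams <- .deepCopy(params)
        }
        if (valF1 > patienceMark + tcfg@minDelta) {
          patienceMark <- valF1
          sinceBest <- 0L
        } else {
          sinceBest <- sinceBest + 1L
          if (sinceBest >= tcfg@patience) break
        }
      }
    }
  })
  model@params <- if (hasVal) bestParams else params
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  if (!is.null(stats)) model@stats <- stats
  if (length(data@vocabulary) == cfg@nClasses)
    model@vocabulary <- data@vocabulary
  model
}

#' Class probabilities for a batch of windows
#'
#' Deterministic evaluation-mode forward pass (no dropout).
#'
#' @param model A \linkS4class{ConvLSTMModel}.
#' @param windows A \linkS4class{WindowedDataset} or a numeric array
#'   \code{n x windowFrames x channels}.
#' @return Numeric matrix \code{n x nClasses}; rows sum to 1; columns named
#'   by the model vocabulary.
#' @export
predictWindowProba <- function(model, windows) {
  stopifnot(is(model, "ConvLSTMModel"))
  X <- if (is(windows, "WindowedDataset")) windows@windows else windows
  if (length(dim(X)) != 3L)
    stop("windows must be an n x frames x channels array")
  cfg <- model@config
  if (dim(X)[3] != cfg@inputChannels)
    stop("window channel count ", dim(X)[3],
         " does not match the model's expected N = ", cfg@inputChannels)
  if (dim(X)[2] != cfg@windowFrames)
    stop("window length ", dim(X)[2],
         " does not match the model's SWS = ", cfg@windowFrames)
  n <- dim(X)[1]
  out <- matrix(NA_real_, n, cfg@nClasses,
                dimnames = list(NULL, model@vocabulary))
  for (s in seq.int(1L, n, by = 512L)) {
    idx <- s:min(s + 511L, n)
    out[idx, ] <- .nnForward(model@params, X[idx, , , drop = FALSE], cfg)$probs
  }
  out
}
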