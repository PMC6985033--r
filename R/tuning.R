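#' @include AllClasses.R convlstm.R evaluate.R
NULL

#' Learning-parameter grid for SGD tuning
#'
#' @param learningRates,momenta Candidate values; defaults are the grids
#'   used for the two-stage search (5 learning rates x 5 momenta = 25
#'   combinations).
#' @return List with the full cartesian grid as a data.frame.
#' @export
learningGrid <- function(learningRates = c(0.0001, 0.001, 0.01, 0.1, 1),
                         momenta = c(0.5, 0.7, 0.9, 0.95, 0.98)) {
  stopifnot(all(learningRates > 0), all(momenta >= 0))
  list(learningRates = learningRates, momenta = momenta,
       grid = expand.grid(learningRate = learningRates, momentum = momenta,
                          KEEP.OUT.ATTRS = FALSE))
}

#' Architecture grid with window-dependent kernel options
#'
#' Kernel sizes are paired with window sizes (5 and 6 frames with a
#' 24-frame window; 6 and 8 frames with a 48-frame window), crossed with
#' the convolution-channel and LSTM-cell options.
#'
#' @param windowFrames Window sizes (default c(24, 48)).
#' @param kernelsByWindow Named list mapping each window size to its kernel
#'   options.
#' @param convChannels,lstmCells Candidate values.
#' @return List describing the grid.
#' @export
architectureGrid <- function(windowFrames = c(24L, 48L),
                             kernelsByWindow = list(`24` = c(5L, 6L),
                                                    `48` = c(6L, 8L)),
                             convChannels = c(32L, 64L, 96L),
                             lstmCells = c(64L, 128L, 192L)) {
  stopifnot(all(as.character(windowFrames) %in% names(kernelsByWindow)))
  list(windowFrames = as.integer(windowFrames),
       kernelsByWindow = kernelsByWindow,
       convChannels = as.integer(convChannels),
       lstmCells = as.integer(lstmCells))
}

#' Enumerate the architecture combinations of a grid
#'
#' Only window/kernel pairings declared in the grid are produced (e.g. an
#' 8-frame kernel is never combined with a 24-frame window).
#'
#' @param grid An \code{\link{architectureGrid}}.
#' @return data.frame with columns \code{windowFrames}, \code{kernelFrames},
#'   \code{convChannels}, \code{lstmCells}.
#' @export
enumerateArchitectureGrid <- function(grid) {
  rows <- list()
  for (w in grid$windowFrames) {
    for (k in grid$kernelsByWindow[[as.character(w)]]) {
      rows[[length(rows) + 1L]] <-
        expand.grid(windowFrames = w, kernelFrames = k,
                    convChannels = grid$convChannels,
                    lstmCells = grid$lstmCells, KEEP.OUT.ATTRS = FALSE)
    }
  }
  do.call(rbind, rows)
}

# train one model on pre-windowed data and return its validation
# window-level micro-F1
.scorePoint <- function(mcfg, tcfg, trainWD, valWD) {
  net <- buildModel(mcfg, vocabulary = trainWD@vocabulary, seed = tcfg@seed)
  net <- trainModel(net, trainWD, valWD, tcfg)
  .windowAccuracy(net@params, mcfg, valWD@windows, valWD@labelIdx)
}

#' Stage 1: grid search over learning rate and momentum
#'
#' Trains one model per grid point with a fixed architecture and selects
#' the point with the best validation window-level micro-averaged F1; ties
#' prefer the lower learning rate, then the lower momentum.  Points whose
#' training aborts (e.g. divergence at a high learning rate) are recorded
#' as failed and excluded from the argmax.
#'
#' @param grid A \code{\link{learningGrid}}.
#' @param mcfg Fixed \linkS4class{ModelConfig}.
#' @param trainWD,valWD Training and validation
#'   \linkS4class{WindowedDataset}s.
#' @param tcfg Base \linkS4class{TrainConfig} (its rate/momentum are
#'   overridden per point).
#' @return List with \code{best} (learningRate, momentum), \code{table}
#'   (score per point, NA for failed points).
#' @export
gridSearchLearning <- function(grid, mcfg, trainWD, valWD,
                               tcfg = trainConfig()) {
  g <- grid$grid
  stopifnot(nrow(g) >= 1)
  g$valF1 <- NA_real_
  for (i in seq_len(nrow(g))) {
    tc <- tcfg
    tc@learningRate <- g$learningRate[i]
    tc@momentum <- g$momentum[i]
    score <- tryCatch(.scorePoint(mcfg, tc, trainWD, valWD),
                      error = function(e) {
                        warning("grid point (lr=", g$learningRate[i],
                                ", mom=", g$momentum[i], ") failed: ",
                                conditionMessage(e))
                        NA_real_
                      })
    g$valF1[i] <- score
  }
  if (all(is.na(g$valF1))) stop("all learning grid points failed")
  ord <- order(-g$valF1, g$learningRate, g$momentum, na.last = TRUE)
  best <- g[ord[1], ]
  list(best = list(learningRate = best$learningRate,
                   momentum = best$momentum),
       table = g)
}

#' Stage 2: grid search over the architecture parameters
#'
#' With the learning rate and momentum fixed to the stage-1 winners, trains
#' one model per window/kernel/channels/cells combination (kernel options
#' paired to window sizes) and selects the best validation window-level
#' micro-F1; ties prefer the smaller model (fewer parameters).  Windowing
#' is redone per window size from the continuous normalized series.
#'
#' @param grid An \code{\link{architectureGrid}}.
#' @param trainSeries,valSeries Normalized continuous series: lists with
#'   \code{values} (frames x channels) and \code{labels}.
#' @param vocabulary Class vocabulary.
#' @param learningRate,momentum Stage-1 winners.
#' @param tcfg Base \linkS4class{TrainConfig}.
#' @return List with \code{best} (a \linkS4class{ModelConfig}),
#'   \code{table} of scores.
#' @export
gridSearchArchitecture <- function(grid, trainSeries, valSeries, vocabulary,
                                   learningRate, momentum,
                                   tcfg = trainConfig()) {
  combos <- enumerateArchitectureGrid(grid)
  combos$valF1 <- NA_real_
  combos$nParams <- NA_integer_
  nCh <- ncol(trainSeries$values)
  wdCache <- list()
  for (i in seq_len(nrow(combos))) {
    w <- combos$windowFrames[i]
    key <- as.character(w)
    if (is.null(wdCache[[key]])) {
      wdCache[[key]] <- list(
        train = makeWindows(trainSeries$values, w, vocabulary = vocabulary,
                            labels = trainSeries$labels),
        val = makeWindows(valSeries$values, w, vocabulary = vocabulary,
                          labels = valSeries$labels))
    }
    mcfg <- modelConfig(windowFrames = w, inputChannels = nCh,
                        kernelFrames = combos$kernelFrames[i],
                        convChannels = combos$convChannels[i],
                        lstmCells = combos$lstmCells[i],
                        nClasses = length(vocabulary))
    tc <- tcfg
    tc@learningRate <- learningRate
    tc@momentum <- momentum
    combos$nParams[i] <- nParameters(mcfg)
    combos$valF1[i] <- tryCatch(
      .scorePoint(mcfg, tc, wdCache[[key]]$train, wdCache[[key]]$val),
      error = function(e) {
        warning("architecture point ", i, " failed: ", conditionMessage(e))
        NA_real_
      })
  }
  if (all(is.na(combos$valF1))) stop("all architecture grid points failed")
  ord <- order(-combos$valF1, combos$nParams, na.last = TRUE)
  b <- combos[ord[1], ]
  best <- modelConfig(windowFrames = b$windowFrames, inputChannels = nCh,
                      kernelFrames = b$kernelFrames,
                      convChannels = b$convChannels, lstmCells = b$lstmCells,
                      nClasses = length(vocabulary))
  list(best = best, table = combos)
}
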