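#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn frameLabels per-frame labels of a marker trial
#' @export
setMethod("frameLabels", "MarkerTrial", function(x) x@frameLabels)

#' @describeIn frameLabels per-frame labels of a channel series
#' @export
setMethod("frameLabels", "ChannelSeries",
          function(x) as.character(colData(x)$label))

#' @describeIn samplingRate sampling rate of a marker trial
#' @export
setMethod("samplingRate", "MarkerTrial", function(x) x@fs)

#' @describeIn samplingRate sampling rate of a channel series
#' @export
setMethod("samplingRate", "ChannelSeries", function(x) metadata(x)$fs)

#' @describeIn athleteId athlete id of a marker trial
#' @export
setMethod("athleteId", "MarkerTrial", function(x) x@athleteId)

#' @describeIn athleteId athlete id of a channel series
#' @export
setMethod("athleteId", "ChannelSeries",
          function(x) metadata(x)$athleteId)

#' @describeIn nFrames frame count of a marker trial
#' @export
setMethod("nFrames", "MarkerTrial", function(x) dim(x@coords)[1])

#' @describeIn nFrames frame count of a channel series
#' @export
setMethod("nFrames", "ChannelSeries", function(x) ncol(x))

#' Channel values as a frames x channels matrix
#'
#' @param x A \linkS4class{ChannelSeries}.
#' @return Numeric matrix, frames in rows, named channels in columns.
#' @export
channelValues <- function(x) {
  stopifnot(is(x, "ChannelSeries"))
  t(assay(x, "channels"))
}

#' Marker coordinates of a trial
#'
#' @param x A \linkS4class{MarkerTrial}.
#' @return Array \code{frames x markers x 3}.
#' @export
markerCoords <- function(x) {
  stopifnot(is(x, "MarkerTrial"))
  x@coords
}

#' Trials of a cohort
#'
#' @param x A \linkS4class{MotionCohort}.
#' @return List of \linkS4class{MarkerTrial}.
#' @export
cohortTrials <- function(x) {
  stopifnot(is(x, "MotionCohort"))
  x@trials
}

#' Athlete ids present in a cohort
#'
#' @param x A \linkS4class{MotionCohort}.
#' @return Character vector of unique athlete ids.
#' @export
cohortAthletes <- function(x) {
  stopifnot(is(x, "MotionCohort"))
  unique(vapply(x@trials, athleteId, character(1)))
}

#' Label vocabulary
#'
#' @param x A \linkS4class{MotionCohort}, \linkS4class{WindowedDataset},
#'   \linkS4class{ConvLSTMModel} or \linkS4class{EvaluationReport}.
#' @return Character vector of class labels (movements first, "Null" last).
#' @export
labelVocabulary <- function(x) {
  if (is(x, "MotionCohort")) return(x@vocabulary)
  if (is(x, "WindowedDataset")) return(x@vocabulary)
  if (is(x, "ConvLSTMModel")) return(x@vocabulary)
  if (is(x, "EvaluationReport")) return(rownames(x@confusion))
  stop("no label vocabulary for objects of class ", class(x))
}

#' Training history of a fitted model
#'
#' @param x A trained \linkS4class{ConvLSTMModel}.
#' @return data.frame with columns \code{epoch}, \code{loss}, \code{valF1}.
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "ConvLSTMModel"))
  x@history
}

#' Confusion matrix of an evaluation report
#'
#' @param x An \linkS4class{EvaluationReport}.
#' @param percent If TRUE, rows are normalized to percentages of the true
#'   class (as confusion matrices are usually displayed).
#' @return Numeric matrix, rows = true classes, columns = predicted.
#' @export
reportConfusion <- function(x, percent = FALSE) {
  stopifnot(is(x, "EvaluationReport"))
  m <- x@confusion
  if (percent) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/") * 100
  }
  m
}

#' Micro- and macro-averaged metrics of a report
#'
#' @param x An \linkS4class{EvaluationReport}.
#' @return Named list with \code{micro}, \code{macro} (each precision,
#'   recall, f1) and \code{perClass} data.frame.
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  list(micro = x@micro, macro = x@macro, perClass = x@perClass)
}

setMethod("show", "BodyModel", function(object) {
  cat("BodyModel:", nrow(object@segments), "segments,",
      nrow(object@markers), "markers\n")
  cat("  segments:", paste(object@segments$segment, collapse = ", "), "\n")
})

setMethod("show", "MovementTemplate", function(object) {
  cat(sprintf("MovementTemplate '%s' (%s, %.2f s, %d pulses)\n",
              object@label, object@side, object@duration,
              nrow(object@pulses)))
})

setMethod("show", "MarkerTrial", function(object) {
  d <- dim(object@coords)
  mv <- unique(setdiff(object@frameLabels, "Null"))
  cat(sprintf("MarkerTrial %s: %d frames x %d markers @ %g Hz [%s]\n",
              object@athleteId, d[1], d[2], object@fs,
              paste(mv, collapse = ",")))
})

setMethod("show", "MotionCohort", function(object) {
  cat(sprintf("MotionCohort: %d trials, %d athletes, classes: %s\n",
              length(object@trials), length(cohortAthletes(object)),
              paste(object@vocabulary, collapse = ", ")))
})

setMethod("show", "WindowedDataset", function(object) {
  d <- dim(object@windows)
  cat(sprintf("WindowedDataset: %d windows of %d frames x %d channels (stride %d)\n",
              d[1], object@windowFrames, d[3], object@strideFrames))
  print(table(factor(object@vocabulary[object@labelIdx],
                     levels = object@vocabulary)))
})

setMethod("show", "ConvLSTMModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ConvLSTMModel (%s): SWS %d, N %d, %d conv (k=%d, C=%d), %d LSTM (L=%d), %d classes\n",
    if (object@trained) "trained" else "untrained",
    cfg@windowFrames, cfg@inputChannels, cfg@convLayers, cfg@kernelFrames,
    cfg@convChannels, cfg@lstmLayers, cfg@lstmCells, cfg@nClasses))
  if (object@trained && nrow(object@history))
    cat(sprintf("  %d epochs, best validation micro-F1 %.4f\n",
                nrow(object@history), max(object@history$valF1, na.rm = TRUE)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d frames, micro-F1 %.4f, macro-F1 %.4f\n",
              object@nFrames, object@micro["f1"], object@macro["f1"]))
})
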