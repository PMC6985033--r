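#' @include AllClasses.R sensorSim.R
NULL

#' Athlete-level train/validation/test split
#'
#' Shuffles the athlete ids with the given seed and assigns
#' \code{floor(n * trainFraction)} athletes to training; the remainder is
#' halved into validation (floor) and test (ceiling).  The split is at the
#' athlete level, so no athlete contributes frames to two subsets.  With
#' the default 2/3 fraction, 417 athletes split into 278/69/70.
#'
#' @param athleteIds Character vector of at least 3 unique ids.
#' @param trainFraction Fraction of athletes used for training (default 2/3).
#' @param seed Integer seed for the shuffle.
#' @return List with character vectors \code{train}, \code{validation},
#'   \code{test}; disjoint, union equals the input.
#' @export
splitAthletes <- function(athleteIds, trainFraction = 2 / 3, seed = 1) {
  athleteIds <- unique(athleteIds)
  n <- length(athleteIds)
  if (n < 3L) stop("at least 3 athletes are required to split")
  stopifnot(trainFraction > 0, trainFraction < 1)
  ids <- withSeed(seed, sample(athleteIds))
  nTrain <- floor(n * trainFraction)
  rem <- n - nTrain
  nVal <- floor(rem / 2)
  list(train = sort(ids[seq_len(nTrain)]),
       validation = sort(ids[nTrain + seq_len(nVal)]),
       test = sort(ids[(nTrain + nVal + 1):n]))
}

#' Fit per-channel normalization statistics
#'
#' Computes the mean and standard deviation of every channel over all
#' training frames pooled across athletes and movements.  The statistics
#' must be fit on the training subset only and reused unchanged for
#' validation and test data.
#'
#' @param x A \linkS4class{ChannelSeries} or a frames x channels matrix of
#'   training data (>= 2 frames).
#' @param epsilon Floor applied to the standard deviation so constant
#'   channels normalize to zero (default 1e-8).
#' @return A \linkS4class{NormalizationStats}.
#' @export
fitNormalization <- function(x, epsilon = 1e-8) {
  v <- if (is(x, "ChannelSeries")) channelValues(x) else as.matrix(x)
  if (nrow(v) < 2L) stop("at least 2 training frames are required")
  mu <- colMeans(v)
  sd <- apply(v, 2, stats::sd)
  new("NormalizationStats", mean = mu, sd = pmax(sd, epsilon),
      epsilon = epsilon)
}

#' Apply normalization statistics to a channel matrix or series
#'
#' @param x A \linkS4class{ChannelSeries} or frames x channels matrix with
#'   the same channels (in the same order) the stats were fit on.
#' @param stats A \linkS4class{NormalizationStats}.
#' @return Object of the same kind as \code{x}, z-normalized channel-wise.
#' @export
applyNormalization <- function(x, stats) {
  stopifnot(is(stats, "NormalizationStats"))
  if (is(x, "ChannelSeries")) {
    v <- assay(x, "channels")
    stopifnot(nrow(v) == length(stats@mean))
    SummarizedExperiment::assay(x, "channels") <-
      (v - stats@mean) / stats@sd
    return(x)
  }
  v <- as.matrix(x)
  stopifnot(ncol(v) == length(stats@mean))
  sweep(sweep(v, 2, stats@mean), 2, stats@sd, "/")
}

#' Concatenate all trials of a subset into one continuous labeled series
#'
#' Row-binds the frames of the given channel series (e.g. every trial of
#' every athlete in the training subset), carrying labels through per frame
#' and recording the trial boundary indices in \code{metadata(x)$boundaries}
#' (the first frame index of each trial after the first).
#'
#' @param seriesList Non-empty list of \linkS4class{ChannelSeries} with
#'   identical channel sets and sampling rates.
#' @return A single \linkS4class{ChannelSeries} (or
#'   \linkS4class{SimulatedIMUSeries} if all inputs are).
#' @export
concatenateAthleteTrials <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  if (length(seriesList) == 1L) return(seriesList[[1]])
  ref <- rownames(seriesList[[1]])
  fs <- samplingRate(seriesList[[1]])
  for (s in seriesList) {
    if (!identical(rownames(s), ref))
      stop("channel sets of the trials do not match")
    if (!identical(samplingRate(s), fs))
      stop("sampling rates of the trials do not match")
  }
  lens <- vapply(seriesList, ncol, integer(1))
  values <- do.call(rbind, lapply(seriesList, channelValues))
  labels <- unlist(lapply(seriesList, frameLabels), use.names = FALSE)
  ids <- unique(vapply(seriesList, function(s) {
    a <- athleteId(s); if (is.null(a)) NA_character_ else a
  }, character(1)))
  cls <- if (all(vapply(seriesList, is, logical(1), "SimulatedIMUSeries")))
    "SimulatedIMUSeries" else "ChannelSeries"
  .newChannelSeries(
    values,
    as.data.frame(rowData(seriesList[[1]])),
    labels, fs,
    if (length(ids) == 1L) ids else NA_character_,
    boundaries = utils::head(cumsum(lens), -1) + 1L,
    class = cls)
}

# majority label of one window of frame labels; ties favour a movement
# class over "Null", then the label occurring earliest in the window
.majorityLabel <- function(labels) {
  tab <- table(labels)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L && any(cand != "Null"))
    cand <- cand[cand != "Null"]
  if (length(cand) > 1L)
    cand <- cand[which.min(match(cand, labels))]
  cand
}

#' Cut a labeled series into sliding windows with majority labels
#'
#' Windows of \code{windowFrames} frames start at frame 1 and advance by
#' \code{strideFrames} (window/4 by default); trailing frames that do not
#' fill a window are dropped.  Each window receives the label of the class
#' occupying the majority of its frames; ties are resolved in favour of a
#' movement class over "Null", then by the earliest occurring label.
#'
#' @param series A \linkS4class{ChannelSeries}, or a frames x channels
#'   matrix (then \code{labels} must be given).
#' @param windowFrames Window size in frames (SWS; 24 or 48 typical).
#' @param strideFrames Stride; default \code{windowFrames / 4} (which must
#'   then be integer).
#' @param vocabulary Label vocabulary; defaults to the movement labels seen
#'   (sorted) followed by "Null".
#' @param labels Per-frame labels when \code{series} is a bare matrix.
#' @return A \linkS4class{WindowedDataset}.
#' @export
makeWindows <- function(series, windowFrames, strideFrames = NULL,
                        vocabulary = NULL, labels = NULL) {
  if (is(series, "ChannelSeries")) {
    values <- channelValues(series)
    labels <- frameLabels(series)
  } else {
    values <- as.matrix(series)
    stopifnot(!is.null(labels), length(labels) == nrow(values))
  }
  windowFrames <- as.integer(windowFrames)
  if (is.null(strideFrames)) {
    if (windowFrames %% 4L != 0L)
      stop("windowFrames must be divisible by 4 for the default stride")
    strideFrames <- windowFrames %/% 4L
  }
  strideFrames <- as.integer(strideFrames)
  n <- nrow(values)
  if (n < windowFrames)
    stop("series (", n, " frames) is shorter than one window (",
         windowFrames, " frames)")
  if (is.null(vocabulary))
    vocabulary <- c(sort(setdiff(unique(labels), "Null")), "Null")
  if (!all(labels %in% vocabulary))
    stop("frame labels outside the vocabulary: ",
         paste(setdiff(labels, vocabulary), collapse = ", "))
  starts <- seq.int(1L, n - windowFrames + 1L, by = strideFrames)
  nw <- length(starts)
  windows <- array(NA_real_, c(nw, windowFrames, ncol(values)),
                   dimnames = list(NULL, NULL, colnames(values)))
  labIdx <- integer(nw)
  for (w in seq_len(nw)) {
    idx <- starts[w]:(starts[w] + windowFrames - 1L)
    windows[w, , ] <- values[idx, ]
    labIdx[w] <- match(.majorityLabel(labels[idx]), vocabulary)
  }
  new("WindowedDataset", windows = windows, labelIdx = labIdx,
      vocabulary = vocabulary, starts = as.integer(starts),
      windowFrames = windowFrames, strideFrames = strideFrames)
}
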