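#' @include AllClasses.R convlstm.R metrics.R
NULL

#' Evaluate a model on one athlete's data, frame by frame
#'
#' All trials of the athlete are concatenated into one continuous series,
#' normalized with the model's training statistics (if supplied), segmented
#' into sliding windows, classified window by window, and fused into
#' per-frame predictions by averaging the probabilities of all windows
#' covering each frame.  The report scores the frame-level predictions
#' against the true frame labels.
#'
#' @param model A trained \linkS4class{ConvLSTMModel}.
#' @param trials List of this athlete's \linkS4class{ChannelSeries} trials
#'   (or a single already-concatenated series).
#' @param stats \linkS4class{NormalizationStats} to apply; defaults to the
#'   stats stored in the model (NULL for none).
#' @param strideFrames Window stride; default SWS/4.
#' @return List with \code{report} (\linkS4class{EvaluationReport}),
#'   \code{predLabels}, \code{trueLabels} and \code{probs} (frames x
#'   classes fused probabilities).
#' @export
evaluateAthlete <- function(model, trials, stats = NULL,
                            strideFrames = NULL) {
  stopifnot(is(model, "ConvLSTMModel"))
  if (is(trials, "ChannelSeries")) trials <- list(trials)
  series <- concatenateAthleteTrials(trials)
  cfg <- model@config
  if (nFrames(series) < cfg@windowFrames)
    stop("athlete has fewer frames (", nFrames(series),
         ") than one window (", cfg@windowFrames, ")")
  if (is.null(stats)) stats <- model@stats
  values <- channelValues(series)
  if (!is.null(stats)) values <- applyNormalization(values, stats)
  trueLabels <- frameLabels(series)
  wd <- makeWindows(values, cfg@windowFrames, strideFrames,
                    vocabulary = model@vocabulary, labels = trueLabels)
  probs <- predictWindowProba(model, wd)
  fused <- frameFusion(probs, wd@starts, cfg@windowFrames, nrow(values))
  predLabels <- model@vocabulary[fused$classIdx]
  report <- precisionRecallF1(
    confusionMatrix(trueLabels, predLabels, model@vocabulary))
  list(report = report, predLabels = predLabels, trueLabels = trueLabels,
       probs = fused$probs)
}

#' Aggregate per-athlete reports into a subset-level report
#'
#' Confusion matrices are summed frame by frame, so the aggregate micro-F1
#' equals the pooled frame accuracy across athletes.
#'
#' @param reports List of \linkS4class{EvaluationReport} with identical
#'   vocabularies.
#' @return A single \linkS4class{EvaluationReport}.
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1)
  conf <- Reduce(`+`, lapply(reports, function(r) r@confusion))
  precisionRecallF1(conf)
}

#' Left/right confusion rate for mirror-pair classes
#'
#' The fraction of frames whose true class is a member of a mirror pair
#' that were predicted as the other member of the same pair — the
#' signature error of sensor sets that carry no chirality information.
#'
#' @param report An \linkS4class{EvaluationReport}.
#' @param pairs Two-column character matrix of paired class labels; by
#'   default every pair of labels in the vocabulary that differ only in a
#'   trailing R/L is used.
#' @return Numeric rate in [0, 1] (0 if no pair frames exist).
#' @export
mirrorConfusionRate <- function(report, pairs = NULL) {
  conf <- report@confusion
  vocab <- rownames(conf)
  if (is.null(pairs)) {
    rights <- vocab[grepl("R$", vocab)]
    lefts <- sub("R$", "L", rights)
    keep <- lefts %in% vocab
    pairs <- cbind(rights[keep], lefts[keep])
  }
  if (!is.matrix(pairs) || nrow(pairs) == 0) return(0)
  confused <- 0; totalPair <- 0
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    confused <- confused + conf[a, b] + conf[b, a]
    totalPair <- totalPair + sum(conf[a, ]) + sum(conf[b, ])
  }
  if (totalPair == 0) return(0)
  confused / totalPair
}

# shared plumbing: extract sIMU channels for every trial of a cohort
# (computed once; sensor configurations subset these channels)
.cohortSimuSeries <- function(cohort, model = buildDefaultBodyModel(),
                              spec = filterSpec(), verbose = FALSE) {
  out <- lapply(seq_along(cohort@trials), function(i) {
    if (verbose && i %% 25 == 0) message("  extracting trial ", i)
    extractSimuChannels(cohort@trials[[i]], model, spec)
  })
  out
}

# group a list of ChannelSeries by athlete id
.groupByAthlete <- function(seriesList) {
  ids <- vapply(seriesList, athleteId, character(1))
  split(seriesList, ids)
}

# train on a subset of channels and evaluate per test athlete
.trainAndEvaluate <- function(seriesList, split, mcfg, tcfg, vocabulary,
                              strideFrames = NULL, verbose = FALSE) {
  byAth <- .groupByAthlete(seriesList)
  trainSeries <- concatenateAthleteTrials(
    unlist(byAth[split$train], recursive = FALSE, use.names = FALSE))
  stats <- fitNormalization(trainSeries)
  normWindows <- function(series) {
    makeWindows(applyNormalization(channelValues(series), stats),
                mcfg@windowFrames, strideFrames,
                vocabulary = vocabulary, labels = frameLabels(series))
  }
  trainWD <- normWindows(trainSeries)
  valWD <- if (length(split$validation)) {
    normWindows(concatenateAthleteTrials(
      unlist(byAth[split$validation], recursive = FALSE, use.names = FALSE)))
  } else NULL
  net <- buildModel(mcfg, vocabulary = vocabulary, seed = tcfg@seed)
  net <- trainModel(net, trainWD, valWD, tcfg, stats = stats,
                    verbose = verbose)
  perAthlete <- lapply(split$test, function(id)
    evaluateAthlete(net, byAth[[id]], stats = stats,
                    strideFrames = strideFrames))
  names(perAthlete) <- split$test
  report <- aggregateReports(lapply(perAthlete, `[[`, "report"))
  list(model = net, report = report, perAthlete = perAthlete)
}

#' Sensor-placement ablation over body-segment combinations
#'
#' For each sensor configuration code: subset the simulated-IMU channels to
#' the configuration's segments, refit the normalization statistics on the
#' training athletes, train a fresh ConvLSTM with the same (tuned)
#' hyperparameters, and evaluate frame-by-frame on the test athletes.
#'
#' @param cohort A \linkS4class{MotionCohort} (or a precomputed list of
#'   \linkS4class{SimulatedIMUSeries}, one per trial, via
#'   \code{simuSeries}).
#' @param configs Character vector of configuration codes (see
#'   \code{\link{sensorConfigTable}}).
#' @param mcfg Template \linkS4class{ModelConfig}; its
#'   \code{inputChannels} is adjusted per configuration.
#' @param tcfg A \linkS4class{TrainConfig}.
#' @param split Athlete split from \code{\link{splitAthletes}}; defaults to
#'   a 2/3 split of the cohort's athletes with \code{tcfg@seed}.
#' @param simuSeries Optional precomputed list of per-trial
#'   \linkS4class{SimulatedIMUSeries}.
#' @param bodyModel,filter Body model and filter used for extraction.
#' @param verbose Print progress.
#' @return List with \code{reports} (named list of
#'   \linkS4class{EvaluationReport}), \code{models}, and \code{table}
#'   (data.frame: config, segments, channels, microF1, macroF1,
#'   mirrorConfusion).
#' @export
runSensorAblation <- function(cohort, configs = names(sensorConfigTable()),
                              mcfg, tcfg, split = NULL, simuSeries = NULL,
                              bodyModel = buildDefaultBodyModel(),
                              filter = filterSpec(), verbose = FALSE) {
  tab <- sensorConfigTable()
  bad <- setdiff(configs, names(tab))
  if (length(bad))
    stop("unknown sensor configuration(s): ", paste(bad, collapse = ", "))
  if (is.null(simuSeries)) {
    stopifnot(is(cohort, "MotionCohort"))
    simuSeries <- .cohortSimuSeries(cohort, bodyModel, filter,
                                    verbose = verbose)
  }
  vocabulary <- if (is(cohort, "MotionCohort")) cohort@vocabulary else
    c(sort(setdiff(unique(unlist(lapply(simuSeries, frameLabels))), "Null")),
      "Null")
  if (is.null(split)) {
    ids <- unique(vapply(simuSeries, athleteId, character(1)))
    split <- splitAthletes(ids, seed = tcfg@seed)
  }
  reports <- list(); models <- list(); rows <- list()
  for (code in configs) {
    if (verbose) message("configuration ", code)
    sub <- lapply(simuSeries, selectSensorConfig, configName = code)
    cfg <- mcfg
    cfg@inputChannels <- nrow(sub[[1]])
    cfg@nClasses <- length(vocabulary)
    res <- tryCatch(
      .trainAndEvaluate(sub, split, cfg, tcfg, vocabulary,
                        verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("configuration ", code, " failed: ", conditionMessage(res))
      next
    }
    reports[[code]] <- res$report
    models[[code]] <- res$model
    rows[[code]] <- data.frame(
      config = code,
      segments = paste(tab[[code]], collapse = "+"),
      channels = cfg@inputChannels,
      microF1 = unname(res$report@micro["f1"]),
      macroF1 = unname(res$report@macro["f1"]),
      mirrorConfusion = mirrorConfusionRate(res$report))
  }
  list(reports = reports, models = models,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       split = split)
}
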