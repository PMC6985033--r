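#' @include AllClasses.R evaluate.R tuning.R io.R
NULL

.experimentDefaults <- function() {
  list(
    cohort = list(nAthletes = 12L, seed = 1L, noiseSd = 0.002,
                  swayAmp = 0.004, ampJitterSd = 0.12, durJitterSd = 0.08,
                  fs = 120, nullLead = 0.4, nullTail = 0.4,
                  movementDuration = 1.6),
    input = list(mode = "sIMU", config = "sIMU13"),
    filter = list(cutoffHz = 15, order = 2L, zeroLag = TRUE),
    split = list(trainFraction = 2 / 3, seed = 1L),
    window = list(windowFrames = 48L, strideFrames = NULL),
    model = list(kernelFrames = 6L, convChannels = 32L, lstmCells = 64L,
                 convLayers = 4L, lstmLayers = 2L, dropoutRate = 0),
    train = list(learningRate = 0.001, momentum = 0.9, batchSize = 100L,
                 maxEpochs = 100L, patience = 10L, seed = 1L),
    output = list(dir = NULL))
}

#' Validate and normalize an experiment configuration
#'
#' Reads a YAML file (or takes a nested list), fills the package defaults
#' (120 Hz, 15 Hz cutoff, batch 100, stride = window/4, 2/3 athlete split),
#' rejects unknown keys, and checks cross-field constraints: the window
#' must survive the convolution stack (see \code{\link{convOutputLength}}),
#' the filter cutoff must be below Nyquist, and the sensor-configuration
#' code must be known.
#'
#' @param cfg Path to a YAML file, or a nested list.
#' @return The normalized configuration list (class
#'   \code{ExperimentConfig}).
#' @export
validateExperimentConfig <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg)) cfg <- list()
  stopifnot(is.list(cfg))
  defaults <- .experimentDefaults()
  badTop <- setdiff(names(cfg), names(defaults))
  if (length(badTop))
    stop("unknown configuration section(s): ", paste(badTop, collapse = ", "))
  for (sec in names(cfg)) {
    badKey <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(badKey))
      stop("unknown key(s) in section '", sec, "': ",
           paste(badKey, collapse = ", "))
  }
  full <- utils::modifyList(defaults, cfg)
  if (is.null(full$window$strideFrames)) {
    if (full$window$windowFrames %% 4L != 0L)
      stop("windowFrames must be divisible by 4 for the default stride")
    full$window$strideFrames <- full$window$windowFrames %/% 4L
  }
  if (full$filter$cutoffHz >= full$cohort$fs / 2)
    stop("filter cutoff ", full$filter$cutoffHz,
         " Hz is not below the Nyquist frequency ", full$cohort$fs / 2, " Hz")
  # feasibility of the convolution stack (errors if infeasible)
  convOutputLength(full$window$windowFrames, full$model$kernelFrames,
                   full$model$convLayers)
  if (full$input$mode == "sIMU" &&
      !full$input$config %in% names(sensorConfigTable()))
    stop("unknown sensor configuration '", full$input$config, "'")
  if (!full$input$mode %in% c("sIMU", "OPT"))
    stop("input mode must be 'sIMU' or 'OPT'")
  structure(full, class = c("ExperimentConfig", "list"))
}

#' Run a full experiment from a declarative configuration
#'
#' Generates the synthetic cohort, derives the requested input channels
#' (optical marker coordinates or a simulated-IMU sensor configuration),
#' splits athletes, fits normalization on the training subset, windows,
#' trains the ConvLSTM, and evaluates frame-by-frame on the test athletes.
#' All artifacts (split manifest, training history, evaluation report,
#' model checkpoint, reproducibility manifest) are written to the output
#' directory.
#'
#' @param cfg An \code{ExperimentConfig} (see
#'   \code{\link{validateExperimentConfig}}); a path or list is validated
#'   first.
#' @param outDir Output directory (overrides \code{cfg$output$dir}; default
#'   a temporary directory).
#' @param verbose Print progress.
#' @return List with \code{report}, \code{model}, \code{split},
#'   \code{table} and \code{dir}.
#' @export
runExperiment <- function(cfg = list(), outDir = NULL, verbose = FALSE) {
  if (!inherits(cfg, "ExperimentConfig")) cfg <- validateExperimentConfig(cfg)
  dir <- outDir %||% cfg$output$dir %||% tempfile("experiment")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cc <- cfg$cohort
  if (verbose) message("generating cohort (", cc$nAthletes, " athletes)")
  cohort <- assembleCohort(
    nAthletes = cc$nAthletes,
    templates = defaultTemplateSet(duration = cc$movementDuration),
    seed = cc$seed, noiseSd = cc$noiseSd, swayAmp = cc$swayAmp,
    ampJitterSd = cc$ampJitterSd, durJitterSd = cc$durJitterSd,
    fs = cc$fs, nullLead = cc$nullLead, nullTail = cc$nullTail)
  fspec <- filterSpec(cfg$filter$cutoffHz, cfg$filter$order,
                      cfg$filter$zeroLag)
  if (verbose) message("deriving input channels (", cfg$input$mode, ")")
  seriesList <- if (cfg$input$mode == "OPT") {
    lapply(cohort@trials, opticalChannels)
  } else {
    lapply(.cohortSimuSeries(cohort, spec = fspec, verbose = verbose),
           selectSensorConfig, configName = cfg$input$config)
  }
  split <- splitAthletes(cohortAthletes(cohort),
                         trainFraction = cfg$split$trainFraction,
                         seed = cfg$split$seed)
  mcfg <- modelConfig(
    windowFrames = cfg$window$windowFrames,
    inputChannels = nrow(seriesList[[1]]),
    kernelFrames = cfg$model$kernelFrames,
    convChannels = cfg$model$convChannels,
    lstmCells = cfg$model$lstmCells,
    nClasses = length(cohort@vocabulary),
    convLayers = cfg$model$convLayers,
    lstmLayers = cfg$model$lstmLayers,
    dropoutRate = cfg$model$dropoutRate)
  tcfg <- trainConfig(
    learningRate = cfg$train$learningRate, momentum = cfg$train$momentum,
    batchSize = cfg$train$batchSize, maxEpochs = cfg$train$maxEpochs,
    patience = cfg$train$patience, seed = cfg$train$seed)
  if (verbose) message("training (", mcfg@inputChannels, " channels)")
  res <- .trainAndEvaluate(seriesList, split, mcfg, tcfg,
                           cohort@vocabulary,
                           strideFrames = cfg$window$strideFrames,
                           verbose = verbose)
  report <- res$report
  jsonlite::write_json(split, file.path(dir, "split.json"),
                       auto_unbox = FALSE)
  utils::write.csv(trainingHistory(res$model),
                   file.path(dir, "history.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(reportConfusion(report)),
                   file.path(dir, "confusion.csv"))
  jsonlite::write_json(
    list(micro = as.list(report@micro), macro = as.list(report@macro),
         nFrames = report@nFrames,
         mirrorConfusion = mirrorConfusionRate(report)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(res$model, file.path(dir, "model.rds"))
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (verbose)
    message(sprintf("test micro-F1 %.4f (%d frames)",
                    report@micro["f1"], report@nFrames))
  list(report = report, model = res$model, split = split,
       perAthlete = res$perAthlete, dir = dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
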