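#' @include AllClasses.R
NULL

#' Write a marker trial to a TRC-style tab-delimited file
#'
#' Writes the standard motion-capture text layout: a header carrying the
#' sampling rate, frame count and marker names, then one row per frame with
#' the frame number, time, and X/Y/Z columns per marker (metres).  The
#' per-frame class labels go to a sidecar tab-delimited file
#' \code{<path>.labels.tsv} with columns \code{frame} and \code{label}.
#'
#' @param trial A \linkS4class{MarkerTrial}.
#' @param path Output file path.
#' @param writeLabels Also write the label sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeTRC <- function(trial, path, writeLabels = TRUE) {
  stopifnot(is(trial, "MarkerTrial"))
  coords <- trial@coords
  n <- dim(coords)[1]
  mk <- dimnames(coords)[[2]]
  fs <- trial@fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    paste(fs, fs, n, length(mk), "m", fs, 1, n, sep = "\t"),
    paste(c("Frame#", "Time", as.vector(rbind(mk, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(mk)),
                           rep(seq_along(mk), each = 3))), collapse = "\t")),
    con)
  flat <- matrix(aperm(coords, c(3, 2, 1)), nrow = n, byrow = TRUE)
  body <- cbind(seq_len(n), (seq_len(n) - 1) / fs, flat)
  utils::write.table(format(body, trim = TRUE, digits = 10), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (writeLabels) {
    utils::write.table(
      data.frame(frame = seq_len(n), label = trial@frameLabels),
      paste0(path, ".labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a marker trial from a TRC-style file
#'
#' Counterpart of \code{\link{writeTRC}}; reads the sampling rate and
#' marker names from the header and, when present, the per-frame labels
#' from \code{<path>.labels.tsv} (otherwise all frames are "Null").
#'
#' @param path TRC file path.
#' @param athleteId Athlete id to record (default "unknown").
#' @return A \linkS4class{MarkerTrial}.
#' @export
readTRC <- function(path, athleteId = "unknown") {
  hdr <- readLines(path, n = 5)
  meta <- strsplit(hdr[3], "\t")[[1]]
  fs <- as.numeric(meta[1])
  nMk <- as.integer(meta[4])
  names4 <- strsplit(hdr[4], "\t")[[1]]
  mk <- names4[-(1:2)]
  mk <- mk[mk != ""][seq_len(nMk)]
  body <- utils::read.table(path, sep = "\t", skip = 5,
                            header = FALSE, fill = TRUE)
  n <- nrow(body)
  flat <- as.matrix(body[, 2 + seq_len(3 * nMk)])
  coords <- aperm(array(t(flat), c(3, nMk, n)), c(3, 2, 1))
  dimnames(coords) <- list(NULL, mk, c("x", "y", "z"))
  labPath <- paste0(path, ".labels.tsv")
  labels <- if (file.exists(labPath)) {
    as.character(utils::read.table(labPath, sep = "\t",
                                   header = TRUE)$label)
  } else rep("Null", n)
  new("MarkerTrial", athleteId = athleteId, coords = coords, fs = fs,
      frameLabels = labels)
}

#' Save / load a cohort as a compact binary container
#'
#' @param cohort A \linkS4class{MotionCohort}.
#' @param path File path (RDS container).
#' @return \code{saveCohort}: \code{path} invisibly; \code{loadCohort}:
#'   the \linkS4class{MotionCohort}.
#' @export
saveCohort <- function(cohort, path) {
  stopifnot(is(cohort, "MotionCohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname saveCohort
#' @export
loadCohort <- function(path) {
  x <- readRDS(path)
  stopifnot(is(x, "MotionCohort"))
  x
}

#' Export a channel series to tidy CSV
#'
#' One row per (frame, channel): frame, time, segment, channel, value,
#' label.
#'
#' @param series A \linkS4class{ChannelSeries}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeChannelCSV <- function(series, path) {
  stopifnot(is(series, "ChannelSeries"))
  v <- channelValues(series)
  fs <- samplingRate(series)
  rd <- rowData(series)
  n <- nrow(v)
  df <- data.frame(
    frame = rep(seq_len(n), ncol(v)),
    time = rep((seq_len(n) - 1) / fs, ncol(v)),
    segment = rep(rd$segment, each = n),
    channel = rep(colnames(v), each = n),
    value = as.vector(v),
    label = rep(frameLabels(series), ncol(v)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
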