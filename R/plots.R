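#' @include AllClasses.R evaluate.R
NULL

#' Plot true vs predicted movement classes over time
#'
#' Timeline view of one athlete's frame-level classification: two horizontal
#' ribbons (true on top, predicted below) coloured by class, the standard
#' way continuous recognition output is inspected for boundary smear and
#' prediction switching.
#'
#' @param evaluation Result of \code{\link{evaluateAthlete}} (list with
#'   \code{trueLabels} and \code{predLabels}).
#' @param vocabulary Class ordering for the colour legend; defaults to the
#'   labels present.
#' @param fs Sampling rate used for the time axis (Hz), default 120.
#' @param file Optional path; when given, a PNG is written there instead of
#'   drawing to the current device.
#' @param main Plot title.
#' @return Invisibly, the colour mapping used.
#' @export
plotPredictionTimeline <- function(evaluation, vocabulary = NULL, fs = 120,
                                   file = NULL, main = "Movement recognition timeline") {
  tl <- evaluation$trueLabels
  pl <- evaluation$predLabels
  stopifnot(length(tl) == length(pl))
  if (is.null(vocabulary))
    vocabulary <- c(sort(setdiff(unique(c(tl, pl)), "Null")), "Null")
  cols <- c(grDevices::hcl.colors(length(vocabulary) - 1, "Dark 3"), "grey85")
  names(cols) <- vocabulary
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 320)
    on.exit(grDevices::dev.off())
  }
  n <- length(tl)
  tt <- (seq_len(n) - 1) / fs
  graphics::plot(NULL, xlim = c(0, tt[n]), ylim = c(0, 2.6), xlab = "time (s)",
                 ylab = "", yaxt = "n", main = main, bty = "n")
  graphics::axis(2, at = c(0.5, 1.9), labels = c("predicted", "true"),
                 tick = FALSE, las = 1)
  graphics::rect(tt - 1 / (2 * fs), 1.5, tt + 1 / (2 * fs), 2.3,
                 col = cols[tl], border = NA)
  graphics::rect(tt - 1 / (2 * fs), 0.1, tt + 1 / (2 * fs), 0.9,
                 col = cols[pl], border = NA)
  graphics::legend("top", legend = vocabulary, fill = cols, horiz = TRUE,
                   bty = "n", cex = 0.7, border = NA)
  invisible(cols)
}
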