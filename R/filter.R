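#' @include AllClasses.R
NULL

#' Low-pass filter specification
#'
#' Defaults follow standard biomechanics practice for marker-derived
#' kinematics: a zero-lag (forward-backward) second-order Butterworth
#' low-pass with a 15 Hz cutoff.
#'
#' @param cutoffHz Cutoff frequency (Hz), default 15.
#' @param order Butterworth order of each pass, default 2.
#' @param zeroLag Apply forward-backward (zero net phase), default TRUE.
#' @return List of class \code{FilterSpec}.
#' @export
filterSpec <- function(cutoffHz = 15, order = 2, zeroLag = TRUE) {
  stopifnot(cutoffHz > 0, order >= 1)
  structure(list(cutoffHz = cutoffHz, order = as.integer(order),
                 zeroLag = isTRUE(zeroLag)),
            class = "FilterSpec")
}

# single-pass IIR with exact DC handling: filtering x - x[1] from zero
# initial state and adding x[1] back is exact for constant inputs because
# the DC gain of a Butterworth low-pass is 1
.lfilterDC <- function(b, a, x) {
  x0 <- x[1]
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x - x0)) + x0
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and then backward so the net
#' phase shift is zero (the effective attenuation is the single-pass
#' magnitude response squared, e.g. gain 0.5 at the cutoff for any order).
#' Edges are handled by odd (point-reflected) padding of
#' \code{3 * (order + 1)} samples at each end, which is removed after
#' filtering; each pass starts from a DC-consistent state so constant
#' series pass through unchanged.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param spec A \code{\link{filterSpec}}.
#' @return Filtered numeric series, same length as \code{x}.
#' @export
zeroLagButterworth <- function(x, fs, spec = filterSpec()) {
  stopifnot(inherits(spec, "FilterSpec"))
  if (spec$cutoffHz >= fs / 2)
    stop("filter cutoff (", spec$cutoffHz, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  n <- length(x)
  pad <- 3L * (spec$order + 1L)
  if (n <= pad)
    stop("series too short to filter: need more than ", pad, " samples")
  bf <- signal::butter(spec$order, spec$cutoffHz / (fs / 2), type = "low")
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- .lfilterDC(bf$b, bf$a, xp)
  if (spec$zeroLag) {
    y <- rev(.lfilterDC(bf$b, bf$a, rev(y)))
  }
  y[(pad + 1):(pad + n)]
}
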