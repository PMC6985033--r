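#' @include AllClasses.R
NULL

#' Frame labels of a labeled series or trial
#'
#' @param x A \linkS4class{MarkerTrial} or \linkS4class{ChannelSeries}.
#' @return Character vector with one class code per frame ("Null" for frames
#'   in which no screened movement is performed).
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' Sampling rate in Hz
#'
#' @param x A \linkS4class{MarkerTrial} or \linkS4class{ChannelSeries}.
#' @return Sampling rate (Hz), numeric scalar.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Athlete identifier
#'
#' @param x A \linkS4class{MarkerTrial} or \linkS4class{ChannelSeries}.
#' @return Character scalar athlete id.
#' @export
setGeneric("athleteId", function(x) standardGeneric("athleteId"))

#' Number of frames
#'
#' @param x A \linkS4class{MarkerTrial} or \linkS4class{ChannelSeries}.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
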