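#' @include AllClasses.R bodyModel.R templates.R kinematics.R
NULL

# evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# forward kinematics: anglesByJoint maps segment name -> n x 3 Cardan
# angles of that segment's joint (rotation relative to its parent);
# rootShift is an n x 3 translation added to the root joint centre.
# Returns coords array n x 45 x 3 (marker names in dimnames[[2]]).
forwardKinematics <- function(model, n, anglesByJoint, rootShift) {
  segs <- model@segments
  markers <- model@markers
  coords <- array(0, c(n, nrow(markers), 3),
                  dimnames = list(NULL, markers$marker, c("x", "y", "z")))
  locBySeg <- lapply(segs$segment, function(s) segmentLocalMarkers(model, s))
  names(locBySeg) <- segs$segment
  idxBySeg <- lapply(segs$segment,
                     function(s) which(markers$segment == s))
  names(idxBySeg) <- segs$segment
  Rs <- vector("list", nrow(segs)); names(Rs) <- segs$segment
  ps <- vector("list", nrow(segs)); names(ps) <- segs$segment
  I3 <- diag(3)
  for (t in seq_len(n)) {
    for (k in seq_len(nrow(segs))) {
      seg <- segs$segment[k]
      off <- c(segs$ox[k], segs$oy[k], segs$oz[k])
      ang <- anglesByJoint[[seg]]
      Rj <- if (is.null(ang)) I3 else eulerToRotation(ang[t, ])
      if (is.na(segs$parent[k])) {
        p <- off + rootShift[t, ]
        R <- Rj
      } else {
        Rp <- Rs[[segs$parent[k]]]
        p <- ps[[segs$parent[k]]] + as.vector(Rp %*% off)
        R <- Rp %*% Rj
      }
      Rs[[seg]] <- R; ps[[seg]] <- p
      loc <- locBySeg[[seg]]
      coords[t, idxBySeg[[seg]], ] <-
        sweep(loc %*% t(R), 2, p, "+")
    }
  }
  coords
}

#' Synthesize one labeled marker trial from a movement template
#'
#' Samples the template's joint-angle and root-translation profiles at
#' \code{fs}, runs forward kinematics through the body model, and brackets
#' the movement with null (quiet standing) lead-in and lead-out periods.
#' Optional athlete-level jitter scales the movement amplitude and duration;
#' optional low-frequency postural sway perturbs the root smoothly over the
#' whole trial; optional isotropic Gaussian noise perturbs every marker
#' coordinate.  The output is a deterministic function of all arguments
#' including \code{seed}.
#'
#' @param template A \linkS4class{MovementTemplate}.
#' @param athleteParams List with \code{amplitudeScale}, \code{durationScale}
#'   (unitless, default 1) and \code{swayAmp} (m, default 0).
#' @param noiseSd Marker noise standard deviation (m), >= 0.
#' @param fs Sampling rate (Hz), default 120.
#' @param nullLead,nullTail Null period durations (s), default 0.5.
#' @param seed Integer seed.
#' @param model A \linkS4class{BodyModel}.
#' @return A \linkS4class{MarkerTrial} whose frame labels are "Null" during
#'   the lead periods and \code{template@label} during the movement.
#' @export
synthesizeTrial <- function(template, athleteParams = list(),
                            noiseSd = 0, fs = 120,
                            nullLead = 0.5, nullTail = 0.5, seed = 1,
                            model = buildDefaultBodyModel()) {
  stopifnot(is(template, "MovementTemplate"), noiseSd >= 0, fs > 0)
  ap <- utils::modifyList(
    list(amplitudeScale = 1, durationScale = 1, swayAmp = 0), athleteParams)
  if (!all(is.finite(c(ap$amplitudeScale, ap$durationScale, ap$swayAmp))))
    stop("athlete jitter parameters must be finite")
  nLead <- round(nullLead * fs)
  nMove <- round(template@duration * ap$durationScale * fs)
  nTail <- round(nullTail * fs)
  if (nMove < 2L) stop("movement too short at this sampling rate")
  n <- nLead + nMove + nTail
  phase <- seq(0, 1, length.out = nMove)
  ev <- evaluateTemplate(template, phase, amplitudeScale = ap$amplitudeScale)
  moveIdx <- (nLead + 1):(nLead + nMove)
  angles <- lapply(ev$angles, function(a) {
    full <- matrix(0, n, 3); full[moveIdx, ] <- a; full
  })
  rootShift <- matrix(0, n, 3)
  rootShift[moveIdx, ] <- ev$root
  withSeed(seed, {
    # smooth low-frequency sway: two random sinusoids per axis
    tt <- (seq_len(n) - 1) / fs
    for (ax in 1:3) {
      for (h in 1:2) {
        amp <- ap$swayAmp * stats::runif(1, 0.4, 1)
        f <- stats::runif(1, 0.2, 0.6)
        ph <- stats::runif(1, 0, 2 * pi)
        rootShift[, ax] <- rootShift[, ax] + amp * sin(2 * pi * f * tt + ph)
      }
    }
    coords <- forwardKinematics(model, n, angles, rootShift)
    if (noiseSd > 0)
      coords <- coords + array(stats::rnorm(length(coords), 0, noiseSd),
                               dim(coords))
    labels <- rep("Null", n)
    labels[moveIdx] <- template@label
    new("MarkerTrial", athleteId = "synthetic", coords = coords,
        fs = fs, frameLabels = labels)
  })
}

#' Assemble a synthetic multi-athlete cohort
#'
#' Generates one trial per movement template for each athlete, with
#' athlete-specific amplitude and timing jitter, postural sway, and marker
#' noise, emulating a movement-screen capture session.  All randomness is
#' driven by \code{seed}; the same call is bit-for-bit reproducible.
#'
#' @param nAthletes Number of athletes (>= 1).
#' @param templates Named list of \linkS4class{MovementTemplate} (default
#'   \code{\link{defaultTemplateSet}()}).
#' @param seed Integer seed.
#' @param noiseSd Marker noise sd (m); default 0.002 (2 mm optical noise).
#' @param swayAmp Postural sway amplitude (m); default 0.004.
#' @param ampJitterSd,durJitterSd Athlete-to-athlete relative sd of movement
#'   amplitude and duration (defaults 0.12, 0.08).
#' @param fs Sampling rate (Hz), default 120.
#' @param nullLead,nullTail Null period durations (s), default 0.4.
#' @param model A \linkS4class{BodyModel}.
#' @return A \linkS4class{MotionCohort} with
#'   \code{nAthletes * length(templates)} trials.
#' @export
assembleCohort <- function(nAthletes, templates = defaultTemplateSet(),
                           seed = 1, noiseSd = 0.002, swayAmp = 0.004,
                           ampJitterSd = 0.12, durJitterSd = 0.08,
                           fs = 120, nullLead = 0.4, nullTail = 0.4,
                           model = buildDefaultBodyModel()) {
  stopifnot(nAthletes >= 1, length(templates) >= 1)
  trials <- vector("list", nAthletes * length(templates))
  k <- 0L
  withSeed(seed, {
    for (i in seq_len(nAthletes)) {
      id <- sprintf("A%03d", i)
      ampA <- max(0.5, 1 + stats::rnorm(1, 0, ampJitterSd))
      durA <- max(0.6, 1 + stats::rnorm(1, 0, durJitterSd))
      for (j in seq_along(templates)) {
        ampT <- ampA * max(0.5, 1 + stats::rnorm(1, 0, 0.03))
        subSeed <- sample.int(.Machine$integer.max - 1L, 1)
        k <- k + 1L
        tr <- synthesizeTrial(
          templates[[j]],
          athleteParams = list(amplitudeScale = ampT, durationScale = durA,
                               swayAmp = swayAmp),
          noiseSd = noiseSd, fs = fs,
          nullLead = nullLead, nullTail = nullTail,
          seed = subSeed, model = model)
        tr@athleteId <- id
        trials[[k]] <- tr
      }
    }
  })
  vocab <- c(vapply(templates, function(t) t@label, character(1)), "Null")
  names(vocab) <- NULL
  new("MotionCohort", trials = trials, vocabulary = vocab,
      seed = as.integer(seed))
}
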