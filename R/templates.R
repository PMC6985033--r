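#' @include AllClasses.R
NULL

# Movement codes used in movement screens, as mirror pairs; bilateral codes
# (DJ) have no partner.
.pairedCodes <- c(HDR = "HDL", HDL = "HDR", BDR = "BDL", BDL = "BDR",
                  TBR = "TBL", TBL = "TBR", SDR = "SDL", SDL = "SDR",
                  LHR = "LHL", LHL = "LHR", LR = "LL", LL = "LR")

# C^2 plateau pulse: smootherstep (6x^5 - 15x^4 + 10x^3) ramps over the
# first and last `edge` fraction of the support, amplitude held in between.
# Zero value, first and second derivative at the support edges; the held
# plateau keeps the posture distinct from quiet standing for most of the
# pulse, so labeled movement frames are recognizably different from Null.
smoothPulse <- function(phase, amplitude, center, width, edge = 0.3) {
  u <- (phase - (center - width / 2)) / width
  s <- function(x) 6 * x^5 - 15 * x^4 + 10 * x^3
  out <- numeric(length(phase))
  rise <- u > 0 & u < edge
  hold <- u >= edge & u <= 1 - edge
  fall <- u > 1 - edge & u < 1
  out[rise] <- amplitude * s(u[rise] / edge)
  out[hold] <- amplitude
  out[fall] <- amplitude * s((1 - u[fall]) / edge)
  out
}

#' Construct a movement template
#'
#' @param label Movement class code.
#' @param side \code{"left"}, \code{"right"} or \code{"bilateral"}.
#' @param duration Movement duration in seconds.
#' @param pulses data.frame of smooth \eqn{\sin^4} pulses (columns
#'   \code{joint}, \code{axis}, \code{amplitude}, \code{center},
#'   \code{width}); see \linkS4class{MovementTemplate}.
#' @return A \linkS4class{MovementTemplate}.
#' @export
movementTemplate <- function(label, side, duration, pulses) {
  new("MovementTemplate", label = label, side = side,
      duration = duration, pulses = pulses)
}

.pulse <- function(joint, axis, amplitude, center = 0.5, width = 0.8) {
  data.frame(joint = joint, axis = axis, amplitude = amplitude,
             center = center, width = width, stringsAsFactors = FALSE)
}

#' Default synthetic movement library
#'
#' Eight distinguishable athletic movements: three left/right mirror pairs
#' (a step-down, a forward lunge, a lateral hop) and two bilateral tasks
#' (a deep squat and a countermovement jump), plus the implicit "Null"
#' standing class.  Chirality is carried by the lower limbs: central
#' segments rotate only about the lateral axis and arm motion is
#' bilaterally symmetric, so torso and upper-arm sensor channels are
#' identical between the members of each mirror pair by construction.
#'
#' @param duration Movement duration in seconds (default 1.6).
#' @return Named list of \linkS4class{MovementTemplate} objects.
#' @export
defaultTemplateSet <- function(duration = 1.6) {
  stepR <- movementTemplate("STEPR", "right", duration, rbind(
    .pulse("shank_R", "x", 1.2),
    .pulse("thigh_R", "x", -0.55),
    .pulse("torso",   "x", 0.25),
    .pulse("root",    "tz", -0.14)))
  lungeR <- movementTemplate("LUNGR", "right", duration, rbind(
    .pulse("thigh_R", "x", -1.00),
    .pulse("shank_R", "x", 1.30),
    .pulse("shank_L", "x", 0.60),
    .pulse("root",    "ty", 0.25),
    .pulse("root",    "tz", -0.20),
    .pulse("torso",   "x", 0.12)))
  hopR <- movementTemplate("HOPR", "right", duration, rbind(
    .pulse("root",    "tx", -0.30, center = 0.5, width = 0.9),
    .pulse("root",    "tz", 0.12, center = 0.30, width = 0.30),
    .pulse("root",    "tz", 0.12, center = 0.70, width = 0.30),
    .pulse("shank_R", "x", 0.55, center = 0.28, width = 0.40),
    .pulse("shank_L", "x", 0.55, center = 0.72, width = 0.40),
    .pulse("thigh_R", "x", -0.30, center = 0.28, width = 0.40)))
  squat <- movementTemplate("SQUAT", "bilateral", duration, rbind(
    .pulse("thigh_L", "x", -0.90), .pulse("thigh_R", "x", -0.90),
    .pulse("shank_L", "x", 1.10),  .pulse("shank_R", "x", 1.10),
    .pulse("root",    "tz", -0.25),
    .pulse("torso",   "x", 0.35),
    .pulse("upper_arm_L", "x", -1.20, width = 0.9),
    .pulse("upper_arm_R", "x", -1.20, width = 0.9)))
  jump <- movementTemplate("JUMP", "bilateral", duration, rbind(
    .pulse("root",  "tz", -0.15, center = 0.30, width = 0.35),
    .pulse("root",  "tz", 0.30, center = 0.62, width = 0.30),
    .pulse("shank_L", "x", 0.80, center = 0.30, width = 0.40),
    .pulse("shank_R", "x", 0.80, center = 0.30, width = 0.40),
    .pulse("upper_arm_L", "x", -0.80, center = 0.40, width = 0.55),
    .pulse("upper_arm_R", "x", -0.80, center = 0.40, width = 0.55)))
  out <- list(stepR, mirrorTemplate(stepR),
              lungeR, mirrorTemplate(lungeR),
              hopR, mirrorTemplate(hopR),
              squat, jump)
  names(out) <- vapply(out, function(t) t@label, character(1))
  out
}

# swap left/right in a joint name ("shank_R" -> "shank_L"); central joints
# and "root" are unchanged
.swapJointSide <- function(joint) {
  out <- joint
  isL <- grepl("_L$", joint)
  isR <- grepl("_R$", joint)
  out[isL] <- sub("_L$", "_R", joint[isL])
  out[isR] <- sub("_R$", "_L", joint[isR])
  out
}

# swap a movement code: known screen codes via the pair table, otherwise
# trailing R <-> L
.swapLabel <- function(label) {
  if (label %in% names(.pairedCodes)) return(unname(.pairedCodes[label]))
  if (grepl("R$", label)) return(sub("R$", "L", label))
  if (grepl("L$", label)) return(sub("L$", "R", label))
  stop("cannot derive the mirrored code for label '", label, "'")
}

#' Mirror a movement template in the sagittal plane
#'
#' Produces the left/right partner of a unilateral movement: left and right
#' joint profiles swap, rotation components about the anterior and vertical
#' axes and lateral translations change sign (rotations about the lateral
#' axis and sagittal-plane translations are preserved by the reflection),
#' and the label swaps to the paired code.  Mirroring is an involution:
#' applying it twice returns the original template exactly.
#'
#' @param template A unilateral \linkS4class{MovementTemplate}.
#' @return The mirrored \linkS4class{MovementTemplate}.
#' @export
mirrorTemplate <- function(template) {
  stopifnot(is(template, "MovementTemplate"))
  if (template@side == "bilateral")
    stop("no mirror is defined for a bilateral template")
  p <- template@pulses
  p$joint <- .swapJointSide(p$joint)
  flip <- p$axis %in% c("y", "z", "tx")
  p$amplitude[flip] <- -p$amplitude[flip]
  new("MovementTemplate",
      label = .swapLabel(template@label),
      side = if (template@side == "right") "left" else "right",
      duration = template@duration, pulses = p)
}

# evaluate all joint angles and the root translation of a template at the
# given phases; returns list(angles = list(joint -> n x 3), root = n x 3)
evaluateTemplate <- function(template, phase, amplitudeScale = 1) {
  p <- template@pulses
  joints <- unique(p$joint[p$axis %in% c("x", "y", "z")])
  angles <- list()
  for (j in joints) {
    a <- matrix(0, length(phase), 3)
    sel <- p$joint == j & p$axis %in% c("x", "y", "z")
    for (i in which(sel)) {
      ax <- match(p$axis[i], c("x", "y", "z"))
      a[, ax] <- a[, ax] + smoothPulse(phase, p$amplitude[i] * amplitudeScale,
                                       p$center[i], p$width[i])
    }
    angles[[j]] <- a
  }
  root <- matrix(0, length(phase), 3)
  sel <- p$joint == "root" & p$axis %in% c("tx", "ty", "tz")
  for (i in which(sel)) {
    ax <- match(p$axis[i], c("tx", "ty", "tz"))
    root[, ax] <- root[, ax] + smoothPulse(phase, p$amplitude[i] * amplitudeScale,
                                           p$center[i], p$width[i])
  }
  list(angles = angles, root = root)
}
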