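#' @include AllClasses.R
NULL

# Local marker coordinates for the left-side limb segments; right-side
# segments are the sagittal mirror (x negated).  Coordinates are metres in
# the segment frame (origin at the proximal joint centre), x lateral
# (+ left), y anterior, z up.
.leftLimbMarkers <- list(
  upper_arm = rbind(c(0.05,  0.04, -0.08),
                    c(0.07, -0.05, -0.16),
                    c(-0.02, 0.06, -0.25)),
  forearm   = rbind(c(0.04,  0.05, -0.06),
                    c(0.06, -0.04, -0.14),
                    c(-0.03, 0.05, -0.21)),
  thigh     = rbind(c(0.07,  0.06, -0.12),
                    c(0.09, -0.06, -0.24),
                    c(-0.02, 0.08, -0.36)),
  shank     = rbind(c(0.05,  0.05, -0.08),
                    c(0.07, -0.05, -0.20),
                    c(-0.03, 0.06, -0.33)),
  foot      = rbind(c(0.00, -0.07, -0.03),
                    c(0.03,  0.16, -0.05),
                    c(0.07,  0.06, -0.04),
                    c(-0.05, 0.06, -0.04))
)

#' Default 13-segment, 45-marker body model
#'
#' Builds the articulated rigid-body model used by the synthetic cohort
#' generator and by segment-pose recovery: pelvis (root), torso, head,
#' and left/right upper arms, forearms, thighs, shanks and feet, carrying
#' 45 named markers (at least three non-collinear per segment).  The model
#' is bilaterally symmetric: local coordinates of right-side segments and
#' the paired markers of the central segments are the sagittal (x-negated)
#' mirror of their left counterparts, so mirrored movements generate exactly
#' mirrored marker clouds.
#'
#' @return A \linkS4class{BodyModel}.
#' @examples
#' model <- buildDefaultBodyModel()
#' model
#' @export
buildDefaultBodyModel <- function() {
  segs <- data.frame(
    segment = c("pelvis", "torso", "head",
                "upper_arm_L", "upper_arm_R", "forearm_L", "forearm_R",
                "thigh_L", "thigh_R", "shank_L", "shank_R",
                "foot_L", "foot_R"),
    parent  = c(NA, "pelvis", "torso",
                "torso", "torso", "upper_arm_L", "upper_arm_R",
                "pelvis", "pelvis", "thigh_L", "thigh_R",
                "shank_L", "shank_R"),
    ox = c(0, 0, 0,  0.22, -0.22, 0, 0,  0.09, -0.09, 0, 0, 0, 0),
    oy = c(0, 0, -0.02, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    oz = c(1.0, 0.12, 0.50, 0.40, 0.40, -0.30, -0.30,
           -0.02, -0.02, -0.42, -0.42, -0.40, -0.40),
    stringsAsFactors = FALSE)

  mk <- function(names, segment, xyz) {
    data.frame(marker = names, segment = segment,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  markers <- rbind(
    mk(c("PELV_ASIS_L", "PELV_ASIS_R", "PELV_PSIS_L", "PELV_PSIS_R"),
       "pelvis",
       rbind(c(0.12, 0.10, 0.00), c(-0.12, 0.10, 0.00),
             c(0.06, -0.12, 0.03), c(-0.06, -0.12, 0.03))),
    mk(c("TORSO_STRN", "TORSO_C7", "TORSO_T10", "TORSO_SHO_L", "TORSO_SHO_R"),
       "torso",
       rbind(c(0, 0.12, 0.25), c(0, -0.08, 0.45), c(0, -0.10, 0.20),
             c(0.20, 0.00, 0.40), c(-0.20, 0.00, 0.40))),
    mk(c("HEAD_FL", "HEAD_FR", "HEAD_BL", "HEAD_BR"), "head",
       rbind(c(0.08, 0.10, 0.12), c(-0.08, 0.10, 0.12),
             c(0.08, -0.10, 0.12), c(-0.08, -0.10, 0.12))))
  for (part in names(.leftLimbMarkers)) {
    loc <- .leftLimbMarkers[[part]]
    n <- nrow(loc)
    markers <- rbind(
      markers,
      mk(sprintf("%s_L_%d", toupper(part), seq_len(n)),
         paste0(part, "_L"), loc),
      mk(sprintf("%s_R_%d", toupper(part), seq_len(n)),
         paste0(part, "_R"), loc * rep(c(-1, 1, 1), each = n)))
  }
  rownames(markers) <- NULL
  new("BodyModel", markers = markers, segments = segs)
}

#' Marker permutation under sagittal mirroring
#'
#' Maps each marker name to the name of the marker occupying its mirrored
#' position when the body is reflected in the sagittal plane: left/right
#' limb markers swap, paired central markers (e.g. the two shoulders) swap,
#' and midline markers map to themselves.
#'
#' @param model A \linkS4class{BodyModel}.
#' @return Named character vector: \code{map[name]} is the mirrored name.
#' @export
mirrorMarkerMap <- function(model) {
  nm <- model@markers$marker
  out <- nm
  has_L <- grepl("_L(_|$)", nm)
  has_R <- grepl("_R(_|$)", nm)
  out[has_L] <- sub("_L(_|$)", "_R\\1", nm[has_L])
  out[has_R] <- sub("_R(_|$)", "_L\\1", nm[has_R])
  fl <- nm == "HEAD_FL"; fr <- nm == "HEAD_FR"
  bl <- nm == "HEAD_BL"; br <- nm == "HEAD_BR"
  out[fl] <- "HEAD_FR"; out[fr] <- "HEAD_FL"
  out[bl] <- "HEAD_BR"; out[br] <- "HEAD_BL"
  names(out) <- nm
  stopifnot(setequal(out, nm))
  out
}

# markers of one segment as an n x 3 matrix of local coordinates
segmentLocalMarkers <- function(model, segment) {
  sel <- model@markers$segment == segment
  m <- as.matrix(model@markers[sel, c("x", "y", "z")])
  rownames(m) <- model@markers$marker[sel]
  m
}

#' Segment names of a body model
#'
#' @param model A \linkS4class{BodyModel}.
#' @return Character vector of the 13 segment names.
#' @export
segmentIds <- function(model) {
  stopifnot(is(model, "BodyModel"))
  model@segments$segment
}

#' Marker names of a body model
#'
#' @param model A \linkS4class{BodyModel}.
#' @return Character vector of the 45 marker names, in model order.
#' @export
markerNames <- function(model) {
  stopifnot(is(model, "BodyModel"))
  model@markers$marker
}
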