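#' @include AllClasses.R
NULL

# elementary rotations, right-handed, radians
rotX <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rotY <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rotZ <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation matrix from Euler/Cardan angles
#'
#' The package convention is the Cardan x-y-z sequence:
#' \code{R = Rx(a) \%*\% Ry(b) \%*\% Rz(c)}.
#'
#' @param angles Numeric length-3 vector (rad).
#' @param sequence Only \code{"xyz"} is implemented.
#' @return 3x3 rotation matrix.
#' @export
eulerToRotation <- function(angles, sequence = "xyz") {
  stopifnot(sequence == "xyz", length(angles) == 3)
  rotX(angles[1]) %*% rotY(angles[2]) %*% rotZ(angles[3])
}

#' Decompose a rotation matrix into Euler/Cardan angles
#'
#' Inverse of \code{\link{eulerToRotation}} for the x-y-z sequence.  In the
#' gimbal-lock configuration (second angle at +/- pi/2, where the first and
#' third rotations become degenerate) the third angle is set to 0 and the
#' result carries attribute \code{gimbal = TRUE}.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param sequence Only \code{"xyz"} is implemented.
#' @param lockTol Threshold on \code{|cos(b)|} below which the gimbal-lock
#'   convention is applied.
#' @return Numeric length-3 vector of angles (rad), principal ranges
#'   \code{a, c} in (-pi, pi], \code{b} in [-pi/2, pi/2]; attribute
#'   \code{gimbal} flags the degenerate configuration.
#' @export
rotationToEuler <- function(R, sequence = "xyz", lockTol = 1e-8) {
  stopifnot(sequence == "xyz")
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  gimbal <- sqrt(R[2, 3]^2 + R[3, 3]^2) < lockTol
  if (gimbal) {
    # cos(b) ~ 0: only (a + sign(b) c) is observable; set c = 0
    a <- atan2(R[3, 2], R[2, 2])
    ang <- c(a, b, 0)
  } else {
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
    ang <- c(a, b, c)
  }
  attr(ang, "gimbal") <- gimbal
  ang
}

#' Least-squares rigid-body pose from marker clouds
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing
#' \eqn{\sum_i \| R\,ref_i + t - obs_i \|^2} (Kabsch/Procrustes solution via
#' SVD of the cross-covariance of the centred clouds, with the determinant
#' correction that excludes reflections).
#'
#' @param observed,reference n x 3 matrices of corresponding marker
#'   positions, n >= 3, reference cloud non-collinear.
#' @return List with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3) and \code{rmse} (root-mean-square residual, m).
#' @export
fitSegmentPose <- function(observed, reference) {
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  if (nrow(observed) < 3L || nrow(reference) < 3L)
    stop("at least 3 markers are required to fit a segment pose")
  stopifnot(nrow(observed) == nrow(reference),
            ncol(observed) == 3L, ncol(reference) == 3L)
  cr <- colMeans(reference); co <- colMeans(observed)
  refC <- sweep(reference, 2, cr); obsC <- sweep(observed, 2, co)
  sv <- svd(refC)$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("reference marker cloud is collinear or degenerate")
  H <- crossprod(refC, obsC)          # sum ref_c obs_c^T
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  t <- co - as.vector(R %*% cr)
  resid <- obsC - refC %*% t(R)
  list(rotation = R, translation = t,
       rmse = sqrt(mean(rowSums(resid^2))))
}

#' Angular velocity from a rotation-matrix series
#'
#' Central-difference angular velocity extracted from the skew-symmetric
#' part of \eqn{\dot R R^T} (global frame); the first and last frames use
#' one-sided differences.
#'
#' @param rotations List of 3x3 rotation matrices, one per frame (>= 3).
#' @param fs Sampling rate (Hz).
#' @return frames x 3 matrix of angular velocity (rad/s).
#' @export
angularVelocitySeries <- function(rotations, fs) {
  n <- length(rotations)
  if (n < 3L) stop("at least 3 frames are required")
  omega <- matrix(0, n, 3)
  for (t in seq_len(n)) {
    if (t == 1L) {
      Rdot <- (rotations[[2]] - rotations[[1]]) * fs
    } else if (t == n) {
      Rdot <- (rotations[[n]] - rotations[[n - 1]]) * fs
    } else {
      Rdot <- (rotations[[t + 1]] - rotations[[t - 1]]) * (fs / 2)
    }
    S <- Rdot %*% t(rotations[[t]])
    W <- (S - t(S)) / 2
    omega[t, ] <- c(W[3, 2], W[1, 3], W[2, 1])
  }
  omega
}

#' Linear acceleration of a point path
#'
#' Second central difference scaled by \code{fs^2}; the first and last
#' frames copy their interior neighbour (mirrored endpoints).
#'
#' @param com frames x 3 matrix of positions (m), >= 3 frames.
#' @param fs Sampling rate (Hz).
#' @return frames x 3 matrix of acceleration (m/s^2).
#' @export
comAccelerationSeries <- function(com, fs) {
  com <- as.matrix(com)
  n <- nrow(com)
  if (n < 3L) stop("at least 3 frames are required")
  a <- matrix(0, n, 3)
  idx <- 2:(n - 1)
  a[idx, ] <- (com[idx + 1, , drop = FALSE] - 2 * com[idx, , drop = FALSE] +
               com[idx - 1, , drop = FALSE]) * fs^2
  a[1, ] <- a[2, ]
  a[n, ] <- a[n - 1, ]
  a
}
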