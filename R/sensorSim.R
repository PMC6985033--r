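#' @include AllClasses.R kinematics.R filter.R bodyModel.R
NULL

# internal constructor for ChannelSeries / SimulatedIMUSeries
.newChannelSeries <- function(values, channelInfo, labels, fs, athleteId,
                              boundaries = integer(), class = "ChannelSeries") {
  se <- SummarizedExperiment(
    assays = list(channels = t(values)),
    rowData = DataFrame(channelInfo),
    colData = DataFrame(label = labels))
  se@metadata <- list(fs = fs, athleteId = athleteId, boundaries = boundaries)
  as(se, class)
}

#' Simulated-IMU channel names for a set of segments
#'
#' @param segments Character vector of segment names.
#' @return Character vector of \code{segment.channel} names, 5 per segment.
#' @export
simuChannelNames <- function(segments) {
  as.vector(vapply(segments, function(s)
    paste(s, c("euler_x", "euler_y", "euler_z", "gyro_norm", "accel_norm"),
          sep = "."), character(5)))
}

#' Extract simulated-IMU channels from a marker trial
#'
#' For every body segment, recovers the per-frame rigid pose from the
#' segment's markers (least-squares fit against the model's local marker
#' coordinates), then computes five channels: the three global-orientation
#' Cardan x-y-z Euler angles (rad, unfiltered), the Euclidean norm of the
#' angular velocity (rad/s), and the Euclidean norm of the linear
#' acceleration of the segment centre of mass (m/s^2), the centre of mass
#' being approximated by the centroid of the segment's markers.  The two
#' norm channels are low-pass filtered per \code{spec}; using norms rather
#' than vector components removes the dependence on sensor axis alignment.
#' Velocities and accelerations are differentiated within the trial, so
#' trials can be concatenated afterwards without seam artefacts.
#'
#' @param trial A \linkS4class{MarkerTrial}.
#' @param model The \linkS4class{BodyModel} the trial's markers follow.
#' @param spec A \code{\link{filterSpec}} (default: 15 Hz zero-lag
#'   second-order Butterworth).
#' @return A \linkS4class{SimulatedIMUSeries} with \code{5 * nSegments}
#'   channels; frame labels are carried through unchanged.
#' @export
extractSimuChannels <- function(trial, model = buildDefaultBodyModel(),
                                spec = filterSpec()) {
  stopifnot(is(trial, "MarkerTrial"))
  coords <- trial@coords
  have <- dimnames(coords)[[2]]
  fs <- trial@fs
  n <- dim(coords)[1]
  # marker trajectories are low-pass filtered before any pose estimation,
  # as in standard optical motion-capture processing: measurement noise on
  # the markers otherwise propagates into the orientation estimates and is
  # amplified by differentiation
  for (mk in seq_len(dim(coords)[2]))
    for (ax in 1:3)
      coords[, mk, ax] <- zeroLagButterworth(coords[, mk, ax], fs, spec)
  segs <- segmentIds(model)
  values <- matrix(NA_real_, n, 5L * length(segs))
  colnames(values) <- simuChannelNames(segs)
  for (seg in segs) {
    loc <- segmentLocalMarkers(model, seg)
    miss <- setdiff(rownames(loc), have)
    if (length(miss))
      stop("marker '", miss[1], "' of segment '", seg,
           "' is missing from the trial")
    obs <- coords[, rownames(loc), , drop = FALSE]
    m <- nrow(loc)
    refC <- sweep(loc, 2, colMeans(loc))
    svRef <- svd(refC)$d
    if (svRef[2] < 1e-10 * max(svRef[1], 1))
      stop("reference marker cloud of segment '", seg, "' is degenerate")
    # centroid path (the segment COM proxy)
    com <- vapply(1:3, function(ax) rowMeans(matrix(obs[, , ax], n, m)),
                  numeric(n))
    # all per-frame cross-covariances in one product:
    # obsC arranged as m x (3 n), column block t holding the centred cloud
    obsC <- matrix(aperm(obs, c(2, 3, 1)), m, 3L * n)
    obsC <- obsC - rep(t(com), each = m)
    Hall <- crossprod(refC, obsC)                # 3 x (3 n)
    rots <- vector("list", n)
    eul <- matrix(0, n, 3)
    for (t in seq_len(n)) {
      dec <- svd(Hall[, (3L * t - 2L):(3L * t)])
      d <- sign(det(dec$v %*% t(dec$u)))
      R <- dec$v %*% (c(1, 1, d) * t(dec$u))
      rots[[t]] <- R
      eul[t, ] <- rotationToEuler(R)
    }
    omega <- angularVelocitySeries(rots, fs)
    acc <- comAccelerationSeries(com, fs)
    # the derivative components are low-pass filtered BEFORE the norm:
    # differentiation amplifies marker noise towards the Nyquist frequency,
    # and once the norm is taken that noise becomes a positive bias that no
    # later filter can remove.  The norm channel then passes the same
    # zero-lag filter.  Both steps are linear or monotone, so the channels
    # remain invariant to a fixed global rotation of the trial.
    for (ax in 1:3) {
      omega[, ax] <- zeroLagButterworth(omega[, ax], fs, spec)
      acc[, ax] <- zeroLagButterworth(acc[, ax], fs, spec)
    }
    gyroNorm <- zeroLagButterworth(sqrt(rowSums(omega^2)), fs, spec)
    accNorm <- zeroLagButterworth(sqrt(rowSums(acc^2)), fs, spec)
    values[, paste(seg, c("euler_x", "euler_y", "euler_z"), sep = ".")] <- eul
    values[, paste(seg, "gyro_norm", sep = ".")] <- gyroNorm
    values[, paste(seg, "accel_norm", sep = ".")] <- accNorm
  }
  info <- data.frame(
    channel = colnames(values),
    segment = rep(segs, each = 5L),
    type = rep(c("euler_x", "euler_y", "euler_z", "gyro_norm", "accel_norm"),
               length(segs)),
    stringsAsFactors = FALSE)
  .newChannelSeries(values, info, trial@frameLabels, fs, trial@athleteId,
                    class = "SimulatedIMUSeries")
}

#' Optical marker channels of a trial
#'
#' Flattens the marker trajectories into a labeled channel series with
#' three channels (x, y, z) per marker — the "OPT" input representation
#' (3 x 45 = 135 channels for the default model).
#'
#' @param trial A \linkS4class{MarkerTrial}.
#' @return A \linkS4class{ChannelSeries}.
#' @export
opticalChannels <- function(trial) {
  stopifnot(is(trial, "MarkerTrial"))
  coords <- trial@coords
  d <- dim(coords)
  mknames <- dimnames(coords)[[2]]
  values <- matrix(NA_real_, d[1], 3 * d[2])
  for (m in seq_len(d[2]))
    values[, (3 * m - 2):(3 * m)] <- coords[, m, ]
  colnames(values) <- as.vector(vapply(
    mknames, function(m) paste(m, c("x", "y", "z"), sep = "."),
    character(3)))
  info <- data.frame(channel = colnames(values),
                     segment = rep(mknames, each = 3L),
                     type = rep(c("x", "y", "z"), d[2]),
                     stringsAsFactors = FALSE)
  .newChannelSeries(values, info, trial@frameLabels, trial@fs,
                    trial@athleteId, class = "ChannelSeries")
}

#' Body-segment combinations used in the sensor-placement ablation
#'
#' @return Named list mapping each configuration code to its segment names:
#'   \code{sIMU1} torso; \code{sIMU2} torso+pelvis; \code{sIMU3L}
#'   torso+shanks; \code{sIMU3U} torso+upper arms; \code{sIMU4}
#'   torso+pelvis+thighs; \code{sIMU4D} forearms+shanks; \code{sIMU4P}
#'   upper arms+thighs; \code{sIMU5} torso+forearms+shanks; \code{sIMU13}
#'   all 13 segments.
#' @export
sensorConfigTable <- function() {
  list(
    sIMU1  = "torso",
    sIMU2  = c("torso", "pelvis"),
    sIMU3L = c("torso", "shank_L", "shank_R"),
    sIMU3U = c("torso", "upper_arm_L", "upper_arm_R"),
    sIMU4  = c("torso", "pelvis", "thigh_L", "thigh_R"),
    sIMU4D = c("forearm_L", "forearm_R", "shank_L", "shank_R"),
    sIMU4P = c("upper_arm_L", "upper_arm_R", "thigh_L", "thigh_R"),
    sIMU5  = c("torso", "forearm_L", "forearm_R", "shank_L", "shank_R"),
    sIMU13 = c("head", "torso", "pelvis", "upper_arm_L", "upper_arm_R",
               "forearm_L", "forearm_R", "thigh_L", "thigh_R",
               "shank_L", "shank_R", "foot_L", "foot_R"))
}

#' Subset a simulated-IMU series to a sensor configuration
#'
#' @param series A \linkS4class{SimulatedIMUSeries}.
#' @param configName One of the codes in \code{\link{sensorConfigTable}}.
#' @return A \linkS4class{SimulatedIMUSeries} restricted to the listed
#'   segments' channels (5 per segment).
#' @export
selectSensorConfig <- function(series, configName) {
  stopifnot(is(series, "SimulatedIMUSeries"))
  tab <- sensorConfigTable()
  if (!configName %in% names(tab))
    stop("unknown sensor configuration '", configName, "'; valid codes: ",
         paste(names(tab), collapse = ", "))
  keep <- rowData(series)$segment %in% tab[[configName]]
  series[keep, ]
}
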