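#' Sensor frame calibration and swing-twist decomposition
#'
#' Raw IMU quaternions arrive in the sensor's right-handed East-North-Up
#' frame.  Two deterministic steps align them with the anatomical model: a
#' limb-class basis permutation into the left-handed Y-up world frame, and a
#' T-pose boresight alignment that removes the per-sensor mounting offset.
#' The relative rotation across a joint is then factored into an axial twist
#' about the limb's long axis and a residual swing that re-points the limb.
#'
#' @name calibration
NULL

#' Basis permutation from sensor ENU to the Y-up world frame
#'
#' Upper-body segments map `c(w, x, y, z)` to `c(w, y, -x, z)`; lower-body
#' segments to `c(w, y, -x, -z)`.  The z-sign difference absorbs the mounting
#' convention of the lower-limb sensors relative to the proximal joint axis.
#'
#' @param q_raw raw quaternion vector or N x 4 matrix
#' @param segment_class `"upper"` or `"lower"`
#' @return permuted quaternion(s), norm preserved exactly
#' @export
coord_permute <- function(q_raw, segment_class = c("upper", "lower")) {
  segment_class <- match.arg(segment_class)
  qm <- .as_quat_mat(q_raw)
  out <- if (segment_class == "upper") {
    cbind(qm[, 1], qm[, 3], -qm[, 2], qm[, 4])
  } else {
    cbind(qm[, 1], qm[, 3], -qm[, 2], -qm[, 4])
  }
  colnames(out) <- NULL
  .quat_shape(out, q_raw)
}

#' Boresight offset from a T-pose capture
#'
#' @param q_tpose world-frame orientation captured at the calibration instant
#' @return the static offset `quat_inverse(q_tpose)`
#' @export
boresight_offset <- function(q_tpose) quat_inverse(q_tpose)

#' Apply the boresight offset to a world-frame orientation
#'
#' `q_offset %q% q_global(t)`; at the calibration instant the result is the
#' identity rotation, so downstream features measure anatomical rotation
#' relative to the reference pose, invariant to how the sensor is strapped on.
#'
#' @param q_global_t world-frame orientation(s) at time t
#' @param q_offset offset from [boresight_offset()]
#' @return calibrated orientation(s)
#' @export
boresight_calibrate <- function(q_global_t, q_offset) {
  quat_multiply(q_offset, q_global_t)
}

#' Relative rotation across a joint
#'
#' `q_rel = q_proximal %q% quat_inverse(q_distal)`, the rotation aligning the
#' distal frame with the proximal frame, isolating joint articulation from
#' shared global heading.
#'
#' @param q_proximal,q_distal unit quaternions (vectors or N x 4 matrices)
#' @return relative rotation(s)
#' @export
relative_rotation <- function(q_proximal, q_distal) {
  quat_multiply(q_proximal, quat_inverse(q_distal))
}

#' Swing-twist decomposition of a relative rotation
#'
#' Factors `q_rel = swing %q% twist` where the twist is the rotation about
#' the anatomical limb axis `axis` (the projection of the vector part onto
#' the axis, renormalized with the scalar part) and the swing is the residual
#' re-pointing rotation.  When the raw twist norm vanishes (a pure 180-degree
#' swing orthogonal to the axis) the twist is taken as the identity and the
#' swing as `q_rel` itself.
#'
#' @param q_rel unit relative rotation (length-4)
#' @param axis unit twist axis, default the limb long axis `c(1, 0, 0)`
#' @return list with unit quaternions `swing`, `twist` and the `axis`
#' @export
swing_twist_decompose <- function(q_rel, axis = c(1, 0, 0)) {
  q_rel <- as.numeric(q_rel)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  v <- q_rel[2:4]
  p <- sum(v * axis) * axis
  raw <- c(q_rel[1], p)
  n <- sqrt(sum(raw^2))
  if (n < 1e-12) {
    twist <- quat_identity()
    swing <- q_rel
  } else {
    twist <- raw / n
    swing <- quat_multiply(q_rel, quat_inverse(twist))
  }
  list(swing = swing, twist = twist, axis = axis)
}

#' Batched swing extraction
#'
#' Row-wise [swing_twist_decompose()] for N x 4 matrices; used when building
#' training targets over whole sequences.
#'
#' @param q_rel N x 4 matrix of unit relative rotations
#' @param axis unit twist axis
#' @return list of N x 4 matrices `swing` and `twist`
#' @export
swing_twist_batch <- function(q_rel, axis = c(1, 0, 0)) {
  qm <- .as_quat_mat(q_rel)
  axis <- axis / sqrt(sum(axis^2))
  proj <- qm[, 2:4, drop = FALSE] %*% axis
  raw <- cbind(qm[, 1], proj %*% t(axis))
  n <- sqrt(rowSums(raw * raw))
  deg <- n < 1e-12
  n[deg] <- 1
  twist <- raw / n
  twist[deg, ] <- rep(quat_identity(), each = sum(deg))
  swing <- quat_multiply(qm, quat_inverse(twist))
  swing[deg, ] <- qm[deg, ]
  list(swing = swing, twist = twist, axis = axis)
}

#' Avatar retargeting calibration
#'
#' From simultaneous T-pose captures of the physical sensor and the avatar
#' joint, computes the constant offset
#' `q_calib = quat_inverse(q_sensor_tpose) %q% q_avatar_tpose` and applies it
#' on the right of the raw sensor orientation: `q_joint = q_raw %q% q_calib`.
#' At the T-pose instant the mapped joint equals the avatar's T-pose joint.
#'
#' @param q_sensor_tpose,q_avatar_tpose unit quaternions captured at T-pose
#' @param q_raw runtime sensor orientation(s)
#' @return avatar joint orientation(s)
#' @export
avatar_calibration <- function(q_sensor_tpose, q_avatar_tpose, q_raw) {
  q_calib <- quat_multiply(quat_inverse(q_sensor_tpose), q_avatar_tpose)
  quat_multiply(q_raw, q_calib)
}
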