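#' Root-relative evaluation suite
#'
#' All evaluation happens in a body-centric reference frame rooted at the
#' sternum: joint positions are reconstructed by forward kinematics along
#' the segment chain with the root fixed at the origin, so global
#' translation drift never enters the metrics.  Reported quantities are the
#' geodesic mean angular error (MAE, degrees), mean per-joint position error
#' (MPJPE, cm), percentage of correct keypoints at fixed thresholds (PCK@5,
#' PCK@10) and integrated over 0-15 cm (PCK-AUC), and the temporal
#' smoothness error (TSE, m/s^2) comparing discrete second derivatives of
#' the trajectories.  Standard deviations use frame-wise aggregation: the
#' per-frame series is the joint-mean at each frame, and sigma is the
#' population standard deviation over frames.
#'
#' @name metrics
NULL

#' Canonical evaluation skeleton
#'
#' Segment topology rooted at the sternum with default lengths (cm):
#' humerus 30, forearm 25, thigh 40, shank 40, lateral shoulder offset 20,
#' lateral hip offset 10.  Each segment stores its parent and its T-pose
#' direction in the Y-up world frame (arms along +/-x, legs down -y).
#'
#' @return data frame with columns `segment`, `parent`, `dx`, `dy`, `dz`,
#'   `length`
#' @export
skeleton_default <- function() {
  data.frame(
    segment = c("left_shoulder", "right_shoulder", "left_upper_arm",
                "right_upper_arm", "left_forearm", "right_forearm",
                "left_hip", "right_hip", "left_thigh", "right_thigh",
                "left_shank", "right_shank"),
    parent = c("sternum", "sternum", "left_shoulder", "right_shoulder",
               "left_upper_arm", "right_upper_arm", "sternum", "sternum",
               "left_hip", "right_hip", "left_thigh", "right_thigh"),
    dx = c(-1, 1, -1, 1, -1, 1, -1, 1, 0, 0, 0, 0),
    dy = c(0, 0, 0, 0, 0, 0, 0, 0, -1, -1, -1, -1),
    dz = rep(0, 12),
    length = c(20, 20, 30, 30, 25, 25, 10, 10, 40, 40, 40, 40),
    stringsAsFactors = FALSE
  )
}

#' Forward kinematics in the body-centric frame
#'
#' Composes per-segment rotations along the chain from the sternum root
#' (fixed at the origin): each segment's global rotation is its parent's
#' global rotation composed with the segment's local rotation, and its
#' endpoint is the parent endpoint displaced by the rotated segment vector.
#'
#' @param skeleton data frame from [skeleton_default()]
#' @param rotations named list of local unit rotation quaternions, one per
#'   skeleton segment (identity = T-pose); the special name `"sternum"` sets
#'   the root rotation (default identity)
#' @return named list with per-segment `position` (endpoint, cm) and
#'   `orientation` (global quaternion)
#' @export
forward_kinematics <- function(skeleton, rotations) {
  missing <- setdiff(skeleton$segment, names(rotations))
  if (length(missing)) {
    stop("missing rotations for segments: ", paste(missing, collapse = ", "))
  }
  g_rot <- list(sternum = if (!is.null(rotations$sternum)) rotations$sternum else quat_identity())
  g_pos <- list(sternum = c(0, 0, 0))
  remaining <- skeleton
  while (nrow(remaining) > 0) {
    ready <- remaining$parent %in% names(g_rot)
    if (!any(ready)) stop("skeleton graph is not rooted at the sternum")
    for (i in which(ready)) {
      seg <- remaining$segment[i]
      par <- remaining$parent[i]
      g_rot[[seg]] <- quat_multiply(g_rot[[par]], rotations[[seg]])
      vec <- c(remaining$dx[i], remaining$dy[i], remaining$dz[i]) * remaining$length[i]
      g_pos[[seg]] <- g_pos[[par]] + quat_rotate(g_rot[[seg]], vec)
    }
    remaining <- remaining[!ready, , drop = FALSE]
  }
  list(position = g_pos, orientation = g_rot)
}

#' Proximal endpoint positions from proximal orientations
#'
#' Maps each predicted joint's proximal-segment orientation to its endpoint
#' (elbow or knee) in the body-centric frame: shoulder/hip mount points come
#' from the torso orientation, and each endpoint displaces its mount point
#' by the rotated limb vector.  During evaluation the proximal orientation
#' is reconstructed from the swing and the sensed distal orientation (for
#' both prediction and ground truth), so axial twist — which the swing
#' target deliberately excludes — never enters the position metrics.
#'
#' @param q_proximal array `[frame, joint, 4]` of proximal-segment
#'   orientations (motion relative to the calibration pose), joints in
#'   [joint_names()] order
#' @param q_torso T x 4 torso orientation matrix (motion relative to T-pose)
#' @param skeleton data frame from [skeleton_default()]
#' @return array `[frame, joint, 3]` of endpoint positions in cm
#' @export
proximal_positions <- function(q_proximal, q_torso,
                               skeleton = skeleton_default()) {
  tt <- dim(q_proximal)[1]
  sk <- skeleton
  row_of <- function(s) which(sk$segment == s)
  mounts <- list(
    left_upper_arm = "left_shoulder", right_upper_arm = "right_shoulder",
    left_upper_leg = "left_hip", right_upper_leg = "right_hip"
  )
  seg_of <- c(left_upper_arm = "left_upper_arm", right_upper_arm = "right_upper_arm",
              left_upper_leg = "left_thigh", right_upper_leg = "right_thigh")
  out <- array(0, c(tt, 4, 3))
  for (j in seq_along(joint_names())) {
    jn <- joint_names()[j]
    mrow <- row_of(mounts[[jn]])
    mvec <- c(sk$dx[mrow], sk$dy[mrow], sk$dz[mrow]) * sk$length[mrow]
    p_mount <- quat_rotate(q_torso, matrix(mvec, tt, 3, byrow = TRUE))
    srow <- row_of(seg_of[[jn]])
    svec <- c(sk$dx[srow], sk$dy[srow], sk$dz[srow]) * sk$length[srow]
    out[, j, ] <- p_mount +
      quat_rotate(q_proximal[, j, , drop = TRUE], matrix(svec, tt, 3, byrow = TRUE))
  }
  out
}

#' Mean per-joint position error (cm)
#' @param pred,gt arrays `[frame, joint, 3]` of root-relative positions (cm)
#' @return scalar MPJPE in cm
#' @export
mpjpe <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  mean(.joint_errors(pred, gt))
}

# per joint-frame Euclidean errors, matrix [frame, joint]
.joint_errors <- function(pred, gt) {
  sqrt(apply((pred - gt)^2, c(1, 2), sum))
}

#' Percentage of correct keypoints
#'
#' 100 times the fraction of joint-frame errors strictly below the
#' threshold.
#'
#' @param errors non-negative Euclidean errors (any shape), cm
#' @param sigma positive threshold, cm
#' @return percentage in `[0, 100]`
#' @export
pck <- function(errors, sigma) {
  if (sigma <= 0) stop("PCK threshold must be positive")
  100 * mean(errors < sigma)
}

#' PCK area under the threshold curve
#'
#' Integrates `PCK(sigma)/100` for thresholds from 0 to `max_sigma` cm and
#' normalizes by the range, so a perfect predictor scores 1.  The integral
#' of the indicator over the range is available in closed form per error
#' (`max_sigma - min(e, max_sigma)`), which equals the limit of the
#' trapezoidal rule on the empirical PCK curve.
#'
#' @param errors non-negative errors, cm
#' @param max_sigma upper threshold (default 15 cm)
#' @return unitless value in `[0, 1]`
#' @export
pck_auc <- function(errors, max_sigma = 15) {
  mean((max_sigma - pmin(errors, max_sigma)) / max_sigma)
}

#' Temporal smoothness error (m/s^2)
#'
#' Discrete accelerations `a_t = (p_{t+1} - 2 p_t + p_{t-1}) / dt^2` are
#' formed from positions converted to meters; the TSE is the mean Euclidean
#' norm of the difference between predicted and true accelerations over the
#' interior frames.
#'
#' @param pred,gt arrays `[frame, joint, 3]` of positions in cm
#' @param dt frame interval in seconds (default 1/60)
#' @return scalar TSE in m/s^2
#' @export
tse <- function(pred, gt, dt = 1 / 60) {
  tt <- dim(pred)[1]
  if (tt < 3) stop("TSE requires at least 3 frames")
  acc <- function(p) {
    pm <- p / 100
    (pm[3:tt, , , drop = FALSE] - 2 * pm[2:(tt - 1), , , drop = FALSE] +
       pm[1:(tt - 2), , , drop = FALSE]) / dt^2
  }
  d <- acc(pred) - acc(gt)
  mean(sqrt(apply(d^2, c(1, 2), sum)))
}

#' Geodesic mean angular error (degrees)
#' @param pred,gt arrays `[frame, joint, 4]` of unit quaternions
#' @return scalar MAE in degrees
#' @export
mae_deg <- function(pred, gt) {
  tt <- dim(pred)[1]; nj <- dim(pred)[2]
  errs <- vapply(seq_len(nj), function(j) {
    geodesic_error_deg(pred[, j, , drop = TRUE], gt[, j, , drop = TRUE])
  }, numeric(tt))
  mean(errs)
}

#' Frame-wise aggregation statistics
#'
#' Joint errors at one frame are correlated through the kinematic chain, so
#' dispersion is reported over frames: the per-frame series is the
#' joint-mean metric at each frame, and sigma is its population standard
#' deviation.  The coefficient of variation is `sigma / mean`.
#'
#' @param frame_series numeric vector of per-frame metric values
#' @return list with `mean`, `sigma` and `cv`
#' @export
framewise_stats <- function(frame_series) {
  if (!length(frame_series)) stop("empty per-frame series")
  m <- mean(frame_series)
  s <- sqrt(mean((frame_series - m)^2))
  list(mean = m, sigma = s, cv = if (m != 0) s / m else 0)
}

#' Full metrics report
#'
#' @param pred_q,gt_q arrays `[frame, joint, 4]` of orientations
#' @param pred_p,gt_p arrays `[frame, joint, 3]` of positions (cm)
#' @param dt frame interval (s)
#' @return a `metrics_report` list mirroring the standard table layout:
#'   MAE/sigma, MPJPE/sigma, PCK\@5, PCK\@10, PCK-AUC, TSE/sigma, plus
#'   per-joint MPJPE breakdown
#' @export
metrics_report <- function(pred_q, gt_q, pred_p, gt_p, dt = 1 / 60) {
  errs <- .joint_errors(pred_p, gt_p)
  tt <- dim(pred_p)[1]
  ang <- vapply(seq_len(dim(pred_q)[2]), function(j) {
    geodesic_error_deg(pred_q[, j, , drop = TRUE], gt_q[, j, , drop = TRUE])
  }, numeric(tt))
  mae_frames <- rowMeans(ang)
  mpjpe_frames <- rowMeans(errs)
  acc <- function(p) {
    pm <- p / 100
    (pm[3:tt, , , drop = FALSE] - 2 * pm[2:(tt - 1), , , drop = FALSE] +
       pm[1:(tt - 2), , , drop = FALSE]) / dt^2
  }
  dacc <- acc(pred_p) - acc(gt_p)
  tse_frames <- rowMeans(sqrt(apply(dacc^2, c(1, 2), sum)))
  s_mae <- framewise_stats(mae_frames)
  s_mp <- framewise_stats(mpjpe_frames)
  s_tse <- framewise_stats(tse_frames)
  structure(list(
    mae_deg = s_mae$mean, sigma_mae = s_mae$sigma,
    mpjpe_cm = s_mp$mean, sigma_mpjpe = s_mp$sigma,
    pck5 = pck(errs, 5), pck10 = pck(errs, 10),
    pck_auc = pck_auc(errs),
    tse = s_tse$mean, sigma_tse = s_tse$sigma,
    per_joint_mpjpe = stats::setNames(colMeans(errs), joint_names()),
    n_frames = tt
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE %.2f deg (sigma %.2f) | MPJPE %.2f cm (sigma %.2f)\n",
              x$mae_deg, x$sigma_mae, x$mpjpe_cm, x$sigma_mpjpe))
  cat(sprintf("PCK@5 %.1f%% | PCK@10 %.1f%% | PCK-AUC %.3f\n",
              x$pck5, x$pck10, x$pck_auc))
  cat(sprintf("TSE %.3f m/s^2 (sigma %.3f) over %d frames\n",
              x$tse, x$sigma_tse, x$n_frames))
  invisible(x)
}
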