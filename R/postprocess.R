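#' Anatomical joint limits and multiplicative Kalman smoothing
#'
#' Raw frame-by-frame regression output can violate physiological limits and
#' carries high-frequency jitter.  Two inference-time repairs are applied in
#' order: deterministic joint-limit clamping (Euler-parameterized bounded
#' constraints, re-projected onto SO(3)), then a scalar-gain multiplicative
#' Kalman filter that blends each new observation with the running estimate
#' on the rotation manifold via the log/exp maps.
#'
#' @name postprocess
NULL

#' Default joint-limit table
#'
#' The elbow and knee are hinge joints with flexion bounded to
#' `[5, 150]` degrees; the shoulder and hip are bounded by an angular box of
#' `[-45, 150]` degrees applied to each intrinsic Y-X-Z Euler axis.  The
#' table is an editable list; [write_joint_limits()] /
#' [read_joint_limits()] round-trip it through JSON.
#'
#' @return named list of per-joint limit specs (`type`, `axis` or `order`,
#'   `lower`, `upper` in degrees)
#' @export
joint_limits_default <- function() {
  box <- list(type = "euler_box", order = "yxz", lower = c(-45, -45, -45),
              upper = c(150, 150, 150))
  hinge <- function(axis) list(type = "hinge", axis = axis, lower = 5, upper = 150)
  list(
    shoulder = box,
    hip = box,
    elbow = hinge(c(0, 0, 1)),
    knee = hinge(c(1, 0, 0))
  )
}

#' @rdname joint_limits_default
#' @param limits a joint-limit list
#' @param path JSON file path
#' @export
write_joint_limits <- function(limits, path) {
  jsonlite::write_json(limits, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname joint_limits_default
#' @export
read_joint_limits <- function(path) {
  lim <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lim, function(l) {
    l$lower <- as.numeric(l$lower); l$upper <- as.numeric(l$upper)
    if (!is.null(l$axis)) l$axis <- as.numeric(l$axis)
    l
  })
}

# intrinsic Y-X-Z Euler angles (radians) of a unit quaternion
.quat_to_euler_yxz <- function(q) {
  M <- quat_to_matrix(q)
  b <- asin(pmin(pmax(-M[2, 3], -1), 1))
  a <- atan2(M[1, 3], M[3, 3])
  g <- atan2(M[2, 1], M[2, 2])
  c(a, b, g)
}

.euler_yxz_to_quat <- function(ang) {
  quat_multiply(quat_from_axis_angle(c(0, 1, 0), ang[1]),
                quat_multiply(quat_from_axis_angle(c(1, 0, 0), ang[2]),
                              quat_from_axis_angle(c(0, 0, 1), ang[3])))
}

#' Clamp a relative rotation to anatomical limits
#'
#' For a hinge joint, the rotation is factored into twist about the hinge
#' axis plus residual swing; the signed twist angle is clamped to the bound
#' and recomposed (in-range pure-hinge inputs are exact fixed points).  For
#' an Euler-box joint, the rotation is mapped to intrinsic Y-X-Z angles,
#' each angle clamped, and the result re-projected onto SO(3).  Joint frames
#' are assumed pre-aligned so the Euler singularity lies outside the
#' anatomical range.
#'
#' @param q_rel unit relative rotation (length-4) or N x 4 matrix
#' @param limit one entry of [joint_limits_default()]
#' @return clamped unit quaternion(s); idempotent
#' @export
clamp_joint_limits <- function(q_rel, limit) {
  if (is.matrix(q_rel)) {
    return(t(apply(q_rel, 1, clamp_joint_limits, limit = limit)))
  }
  q_rel <- quat_canonicalize(quat_normalize(q_rel))
  if (limit$type == "hinge") {
    st <- swing_twist_decompose(q_rel, axis = limit$axis)
    tw <- st$twist
    ang <- 2 * atan2(sum(tw[2:4] * st$axis), tw[1])   # signed angle about axis
    ang <- ang * 180 / pi
    ang_cl <- pmin(pmax(ang, limit$lower), limit$upper)
    if (isTRUE(all.equal(ang, ang_cl, tolerance = 1e-12))) return(q_rel)
    tw_cl <- quat_from_axis_angle(st$axis, ang_cl * pi / 180)
    quat_canonicalize(quat_normalize(quat_multiply(st$swing, tw_cl)))
  } else if (limit$type == "euler_box") {
    ang <- .quat_to_euler_yxz(q_rel) * 180 / pi
    ang_cl <- pmin(pmax(ang, limit$lower), limit$upper)
    if (isTRUE(all.equal(ang, ang_cl, tolerance = 1e-12))) return(q_rel)
    quat_canonicalize(quat_normalize(.euler_yxz_to_quat(ang_cl * pi / 180)))
  } else {
    stop("unknown joint-limit type: ", limit$type)
  }
}

#' Initialize an orientation filter state
#'
#' @param q0 initial orientation estimate
#' @param sigma_p2 process-noise variance (default 1e-6)
#' @param sigma_m2 measurement-noise variance (default 1e-3)
#' @param P0 initial error covariance (default `sigma_m2`)
#' @return a `filter_state` list
#' @export
mekf_init <- function(q0 = quat_identity(), sigma_p2 = 1e-6,
                      sigma_m2 = 1e-3, P0 = sigma_m2) {
  structure(list(q_hat = quat_normalize(q0), P = P0,
                 sigma_p2 = sigma_p2, sigma_m2 = sigma_m2),
            class = "filter_state")
}

#' One multiplicative Kalman update
#'
#' Gain `K = (P + sigma_p2) / (P + sigma_p2 + sigma_m2)`; the rotational
#' residual `log(q_obs %q% q_hat^-1)` is scaled by `K` in the tangent space
#' and re-applied through the exponential map, so the update interpolates
#' geodesically between the prior estimate and the observation and stays on
#' the unit sphere to numerical precision.  The covariance follows the
#' standard scalar form `P <- (1 - K) (P + sigma_p2)`, which converges to
#' the stationary gain implied by constant process noise.
#'
#' @param state a `filter_state`
#' @param q_obs unit observation quaternion
#' @return updated `filter_state`
#' @export
mekf_update <- function(state, q_obs) {
  S <- state$P + state$sigma_p2
  K <- S / (S + state$sigma_m2)
  resid <- quat_log(quat_multiply(q_obs, quat_inverse(state$q_hat)))
  state$q_hat <- quat_normalize(
    quat_multiply(quat_exp(K * resid), state$q_hat))
  state$P <- (1 - K) * S
  state
}

#' Smooth a quaternion series with the scalar-gain filter
#'
#' @param q_series N x 4 matrix of unit observations (one joint)
#' @param ... passed to [mekf_init()]; the state is initialized at the first
#'   observation
#' @return N x 4 matrix of filtered unit quaternions
#' @export
mekf_smooth <- function(q_series, ...) {
  qm <- .as_quat_mat(q_series)
  st <- mekf_init(qm[1, ], ...)
  out <- matrix(0, nrow(qm), 4)
  out[1, ] <- st$q_hat
  if (nrow(qm) > 1) {
    for (i in 2:nrow(qm)) {
      st <- mekf_update(st, qm[i, ])
      out[i, ] <- st$q_hat
    }
  }
  out
}

#' Apply the full post-processing stack to a prediction series
#'
#' Clamps each joint's swing to its anatomical limits first (clamping a
#' filtered state could re-introduce jumps), then smooths each joint series
#' with the multiplicative Kalman filter.
#'
#' @param pred N x 40 prediction matrix in the canonical joint layout
#' @param limits joint-limit table; per predicted joint the shoulder box is
#'   used for upper arms and the hip box for upper legs
#' @param smooth logical; apply the Kalman stage (default TRUE)
#' @return post-processed N x 40 matrix
#' @export
postprocess_predictions <- function(pred, limits = joint_limits_default(),
                                    smooth = TRUE) {
  out <- pred
  lim_for <- list(limits$shoulder, limits$shoulder, limits$hip, limits$hip)
  for (j in 1:4) {
    qc <- (j - 1L) * 10L + 1:4
    qs <- clamp_joint_limits(pred[, qc, drop = FALSE], lim_for[[j]])
    if (smooth) qs <- mekf_smooth(qs)
    out[, qc] <- qs
  }
  out
}
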