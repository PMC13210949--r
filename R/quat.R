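#' Quaternion algebra for articulated motion
#'
#' All quaternions in this package are stored scalar-first, `c(w, x, y, z)`,
#' in the Hamilton convention: `quat_multiply(q1, q2)` composes rotations so
#' that `q2` is applied first and `q1` second, matching the pre-multiplied
#' boresight calibration `q_offset %q% q_global(t)`.  Functions accept either
#' a length-4 numeric vector or an N x 4 matrix (one quaternion per row) and
#' return the same shape.
#'
#' @name quat
NULL

.as_quat_mat <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternions must have 4 columns (w, x, y, z)")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion is a length-4 numeric (w, x, y, z)")
    matrix(q, nrow = 1L)
  }
}

.quat_shape <- function(out, template) {
  if (is.matrix(template)) out else drop(out)
}

#' Quaternion identity
#' @return the identity rotation `c(1, 0, 0, 0)`
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Euclidean norm of quaternion rows
#' @param q quaternion vector or N x 4 matrix
#' @return numeric vector of norms
#' @export
quat_norm <- function(q) {
  qm <- .as_quat_mat(q)
  sqrt(rowSums(qm * qm))
}

#' Normalize quaternions to unit norm
#' @inheritParams quat_norm
#' @return unit quaternion(s), same shape as the input
#' @export
quat_normalize <- function(q) {
  qm <- .as_quat_mat(q)
  if (any(!is.finite(qm))) stop("non-finite quaternion")
  n <- sqrt(rowSums(qm * qm))
  if (any(n < 1e-12)) stop("cannot normalize a zero quaternion")
  .quat_shape(qm / n, q)
}

#' Hamilton product of quaternions
#'
#' Composes rotations: the result applies `q2` first, then `q1`.  The output
#' norm equals the product of the input norms, so unit inputs give a unit
#' output.
#'
#' @param q1,q2 quaternion vectors or conformable N x 4 matrices (one of the
#'   two may be a single quaternion, which is recycled)
#' @return composed quaternion(s)
#' @export
quat_multiply <- function(q1, q2) {
  a <- .as_quat_mat(q1); b <- .as_quat_mat(q2)
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite quaternion")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w1 <- a[, 1]; x1 <- a[, 2]; y1 <- a[, 3]; z1 <- a[, 4]
  w2 <- b[, 1]; x2 <- b[, 2]; y2 <- b[, 3]; z2 <- b[, 4]
  out <- cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
  colnames(out) <- NULL
  if (is.matrix(q1) || is.matrix(q2)) out else drop(out)
}

#' Infix Hamilton product
#' @rdname quat_multiply
#' @usage q1 \%q\% q2
#' @export
`%q%` <- function(q1, q2) quat_multiply(q1, q2)

#' Quaternion inverse (conjugate of a unit quaternion)
#'
#' For unit quaternions the inverse is the conjugate
#' `c(w, -x, -y, -z)`; `q %q% quat_inverse(q)` is the identity.
#'
#' @inheritParams quat_norm
#' @return inverse quaternion(s)
#' @export
quat_inverse <- function(q) {
  qm <- .as_quat_mat(q)
  if (any(!is.finite(qm))) stop("non-finite quaternion")
  n2 <- rowSums(qm * qm)
  if (any(n2 < 1e-24)) stop("cannot invert a zero quaternion")
  out <- cbind(qm[, 1], -qm[, 2], -qm[, 3], -qm[, 4]) / n2
  colnames(out) <- NULL
  .quat_shape(out, q)
}

#' Canonicalize quaternion sign so that w >= 0
#'
#' `q` and `-q` encode the same rotation; serialization boundaries use the
#' w-nonnegative representative.  Never applied inside loss gradients.
#'
#' @inheritParams quat_norm
#' @return sign-canonicalized quaternion(s)
#' @export
quat_canonicalize <- function(q) {
  qm <- .as_quat_mat(q)
  s <- ifelse(qm[, 1] < 0, -1, 1)
  .quat_shape(qm * s, q)
}

#' Rotate 3-vectors by quaternions
#' @param q unit quaternion vector or N x 4 matrix
#' @param v 3-vector or N x 3 matrix
#' @return rotated vector(s), same shape as `v`
#' @export
quat_rotate <- function(q, v) {
  qm <- .as_quat_mat(q)
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (nrow(qm) == 1L && nrow(vm) > 1L) qm <- qm[rep(1L, nrow(vm)), , drop = FALSE]
  if (nrow(vm) == 1L && nrow(qm) > 1L) vm <- vm[rep(1L, nrow(qm)), , drop = FALSE]
  # v' = v + 2 u x (u x v + w v), u = vector part
  u <- qm[, 2:4, drop = FALSE]
  w <- qm[, 1]
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  t1 <- cross(u, vm) + w * vm
  out <- vm + 2 * cross(u, t1)
  if (is.matrix(v)) out else drop(out)
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion (length 4)
#' @return 3 x 3 rotation matrix
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Axis-angle constructor
#' @param axis 3-vector rotation axis (normalized internally)
#' @param angle rotation angle in radians
#' @return unit quaternion
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero rotation axis")
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Logarithm map: unit quaternion to rotation vector
#'
#' Maps a unit quaternion to the tangent space of SO(3): the result is
#' `theta * axis` with `theta` the rotation angle in radians.  Near the
#' identity a series expansion avoids division by a vanishing sine.
#'
#' @param q unit quaternion vector or N x 4 matrix
#' @return rotation 3-vector (or N x 3 matrix)
#' @export
quat_log <- function(q) {
  qm <- .as_quat_mat(q)
  # work on the w >= 0 cover so the angle is in [0, pi]
  s <- ifelse(qm[, 1] < 0, -1, 1)
  qm <- qm * s
  w <- pmin(qm[, 1], 1)
  vn <- sqrt(rowSums(qm[, 2:4, drop = FALSE]^2))
  theta <- 2 * atan2(vn, w)
  # theta / (2 sin(theta/2)) -> 1 + theta^2/24 + ... as theta -> 0
  half <- theta / 2
  scale <- ifelse(vn < 1e-8, 2 * (1 + half^2 / 6), theta / vn)
  out <- qm[, 2:4, drop = FALSE] * scale
  if (is.matrix(q)) out else drop(out)
}

#' Exponential map: rotation vector to unit quaternion
#' @param v rotation 3-vector (`theta * axis`) or N x 3 matrix
#' @return unit quaternion (or N x 4 matrix)
#' @export
quat_exp <- function(v) {
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (any(!is.finite(vm))) stop("non-finite rotation vector")
  theta <- sqrt(rowSums(vm * vm))
  half <- theta / 2
  # sin(theta/2)/theta -> 1/2 - theta^2/48 as theta -> 0
  k <- ifelse(theta < 1e-8, 0.5 - theta^2 / 48, sin(half) / theta)
  out <- cbind(cos(half), vm * k)
  colnames(out) <- NULL
  if (is.matrix(v)) out else drop(out)
}

#' Geodesic angular error between rotations, in degrees
#'
#' Computes `2 * acos(|w(dq)|) * 180 / pi` with `dq = q_hat %q% q_gt^-1`.
#' Taking the absolute scalar part respects the double cover of SO(3): `q`
#' and `-q` are the same rotation, so antipodal pairs score zero error.
#'
#' @param q_hat,q_gt unit quaternion vectors or N x 4 matrices
#' @return angular error(s) in `[0, 180]` degrees
#' @export
geodesic_error_deg <- function(q_hat, q_gt) {
  dq <- quat_multiply(q_hat, quat_inverse(q_gt))
  dm <- .as_quat_mat(dq)
  w <- pmin(pmax(abs(dm[, 1]), 0), 1)
  2 * acos(w) * 180 / pi
}
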