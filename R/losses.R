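#' Physics-informed multi-task objective
#'
#' The training loss combines a manifold-aware quaternion cosine term with
#' Huber (smooth-L1) penalties on the predicted angular velocity and linear
#' acceleration of the proximal joints:
#' `L = lambda_q * L_quat + lambda_w * L_vel + lambda_a * L_acc`.
#' The quaternion term `1 - |q_hat . q_gt|` is invariant to the antipodal
#' sign ambiguity of unit quaternions (q and -q are one rotation).  The
#' velocity term is the driver of the hard-negative strategy: it penalizes
#' spurious proximal motion when the true joint is still.  The acceleration
#' term is a light smoothness/gravity-consistency regularizer.
#'
#' @name losses
NULL

#' Loss weights
#' @param lambda_q,lambda_w,lambda_a non-negative term weights; the defaults
#'   (1.0, 0.1, 0.01) are the critically damped operating point
#' @return list of weights
#' @export
loss_weights <- function(lambda_q = 1.0, lambda_w = 0.1, lambda_a = 0.01) {
  stopifnot(lambda_q >= 0, lambda_w >= 0, lambda_a >= 0)
  list(lambda_q = lambda_q, lambda_w = lambda_w, lambda_a = lambda_a)
}

# column index helpers into the 40-dim target layout
.quat_cols <- function() as.vector(vapply(1:4, function(j) (j - 1L) * 10L + 1:4, integer(4)))
.vel_cols <- function() as.vector(vapply(1:4, function(j) (j - 1L) * 10L + 5:7, integer(3)))
.acc_cols <- function() as.vector(vapply(1:4, function(j) (j - 1L) * 10L + 8:10, integer(3)))

#' Quaternion cosine loss
#'
#' Mean over batch and joints of `1 - |q_hat . q_gt|` for unit quaternions;
#' zero iff every prediction equals its target up to sign, and at most 1.
#'
#' @param q_hat,q_gt N x 4 matrices of unit quaternions (rows paired)
#' @return scalar loss
#' @export
quat_cosine_loss <- function(q_hat, q_gt) {
  d <- rowSums(.as_quat_mat(q_hat) * .as_quat_mat(q_gt))
  mean(1 - abs(d))
}

.huber <- function(e) ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
.huber_grad <- function(e) ifelse(abs(e) < 1, e, sign(e))

#' Huber angular-velocity loss
#'
#' Mean over all joint/axis components of the smooth-L1 penalty with knee at
#' 1: quadratic `0.5 e^2` for `|e| < 1`, linear `|e| - 0.5` otherwise (the
#' branches agree at the knee).
#'
#' @param w_hat,w_gt matrices of predicted / true angular-velocity
#'   components (any conformable shape)
#' @return scalar loss
#' @export
huber_velocity_loss <- function(w_hat, w_gt) {
  mean(.huber(w_hat - w_gt))
}

#' Huber linear-acceleration loss
#' @param a_hat,a_gt matrices of predicted / true acceleration components
#' @return scalar loss; same contract as [huber_velocity_loss()]
#' @export
huber_acceleration_loss <- function(a_hat, a_gt) {
  mean(.huber(a_hat - a_gt))
}

#' Total multi-task loss with per-term breakdown and gradient
#'
#' Operates on B x 40 prediction/target matrices in the canonical joint
#' layout.  Predicted quaternion blocks are assumed unit-normalized (the
#' model normalizes them before the loss).  Optionally restricts the
#' velocity term to hard-negative rows (`vel_scope = "hardneg"`); the
#' default applies it to every sample.
#'
#' @param pred,target B x 40 matrices
#' @param weights [loss_weights()]
#' @param hard logical vector marking hard-negative rows (used only when
#'   `vel_scope = "hardneg"`)
#' @param vel_scope `"all"` or `"hardneg"`
#' @param grad logical; also return the gradient with respect to `pred`
#' @return list with `total`, `quat`, `vel`, `acc` and optionally `grad`
#'   (B x 40)
#' @export
total_loss <- function(pred, target, weights = loss_weights(), hard = NULL,
                       vel_scope = c("all", "hardneg"), grad = FALSE) {
  vel_scope <- match.arg(vel_scope)
  B <- nrow(pred)
  qc <- .quat_cols(); vc <- .vel_cols(); ac <- .acc_cols()

  dots <- matrix(0, B, 4)
  for (j in 1:4) {
    cols <- (j - 1L) * 10L + 1:4
    dots[, j] <- rowSums(pred[, cols, drop = FALSE] * target[, cols, drop = FALSE])
  }
  l_quat <- mean(1 - abs(dots))

  vel_rows <- if (vel_scope == "hardneg" && !is.null(hard)) which(hard) else seq_len(B)
  ev <- pred[vel_rows, vc, drop = FALSE] - target[vel_rows, vc, drop = FALSE]
  l_vel <- if (length(vel_rows)) mean(.huber(ev)) else 0
  ea <- pred[, ac, drop = FALSE] - target[, ac, drop = FALSE]
  l_acc <- mean(.huber(ea))

  total <- weights$lambda_q * l_quat + weights$lambda_w * l_vel +
    weights$lambda_a * l_acc
  out <- list(total = total, quat = l_quat, vel = l_vel, acc = l_acc)

  if (grad) {
    g <- matrix(0, B, 40)
    for (j in 1:4) {
      cols <- (j - 1L) * 10L + 1:4
      s <- sign(dots[, j])
      s[s == 0] <- 1
      g[, cols] <- -weights$lambda_q * s * target[, cols, drop = FALSE] / (B * 4)
    }
    if (length(vel_rows)) {
      g[vel_rows, vc] <- weights$lambda_w * .huber_grad(ev) / length(ev)
    }
    g[, ac] <- weights$lambda_a * .huber_grad(ea) / length(ea)
    out$grad <- g
  }
  out
}
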