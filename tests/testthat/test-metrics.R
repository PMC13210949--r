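identity_rotations <- function() {
  sk <- skeleton_default()
  rots <- stats::setNames(rep(list(quat_identity()), nrow(sk)), sk$segment)
  rots
}

test_that("forward kinematics reproduces the T-pose and simple chains", {
  sk <- skeleton_default()
  fk <- forward_kinematics(sk, identity_rotations())
  # identity rotations: canonical T-pose offsets
  expect_equal(fk$position$left_shoulder, c(-20, 0, 0))
  expect_equal(fk$position$left_upper_arm, c(-50, 0, 0))
  expect_equal(fk$position$left_forearm, c(-75, 0, 0))   # sum of segment vectors
  expect_equal(fk$position$right_forearm, c(75, 0, 0))
  expect_equal(fk$position$left_shank, c(-10, -80, 0))
  # 90-degree shoulder rotation moves the elbow by the humeral length
  rots <- identity_rotations()
  rots$right_upper_arm <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  fk2 <- forward_kinematics(sk, rots)
  expect_equal(fk2$position$right_upper_arm, c(20, 30, 0), tolerance = 1e-12)
  d <- sqrt(sum((fk2$position$right_upper_arm - fk2$position$right_shoulder)^2))
  expect_equal(d, 30)
  expect_error(forward_kinematics(sk, rots[-1]), "missing rotations")
})

test_that("forward kinematics preserves segment lengths under random rotations", {
  sk <- skeleton_default()
  qs <- random_unit_quats(nrow(sk) + 1, seed = 31)
  rots <- stats::setNames(lapply(seq_len(nrow(sk)), function(i) qs[i, ]),
                          sk$segment)
  rots$sternum <- qs[nrow(sk) + 1, ]
  fk <- forward_kinematics(sk, rots)
  for (i in seq_len(nrow(sk))) {
    par <- sk$parent[i]
    p0 <- if (par == "sternum") c(0, 0, 0) else fk$position[[par]]
    expect_equal(sqrt(sum((fk$position[[sk$segment[i]]] - p0)^2)),
                 sk$length[i], tolerance = 1e-9)
  }
})

test_that("MPJPE matches hand-computed distances", {
  p <- array(0, c(1, 1, 3)); g <- array(0, c(1, 1, 3))
  expect_equal(mpjpe(p, g), 0)
  p[1, 1, ] <- c(3, 0, 0)
  expect_equal(mpjpe(p, g), 3)
  # never exceeds the largest per-joint error
  set.seed(41)
  p2 <- array(rnorm(10 * 4 * 3), c(10, 4, 3)); g2 <- array(rnorm(120), c(10, 4, 3))
  errs <- sqrt(apply((p2 - g2)^2, c(1, 2), sum))
  expect_lte(mpjpe(p2, g2), max(errs))
})

test_that("PCK uses a strict threshold and is monotone in sigma", {
  expect_equal(pck(rep(1, 10), 5), 100)
  expect_equal(pck(c(3, 7), 5), 50)
  expect_equal(pck(c(5, 5), 5), 0)   # error exactly at sigma is excluded
  expect_error(pck(c(1), 0), "positive")
  set.seed(42)
  e <- rexp(500, 1 / 5)
  sig <- seq(0.5, 20, by = 0.5)
  vals <- vapply(sig, function(s) pck(e, s), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("PCK-AUC equals the survival-function oracle and its anchors", {
  expect_equal(pck_auc(rep(0, 5)), 1)
  expect_equal(pck_auc(rep(20, 5)), 0)
  expect_equal(pck_auc(rep(7.5, 5)), 0.5)
  # trapezoid-on-the-curve oracle at fine resolution
  set.seed(43)
  e <- rexp(300, 1 / 6)
  grid <- seq(0, 15, by = 0.001)
  curve <- vapply(grid, function(s) mean(e < s), numeric(1))
  trap <- sum((curve[-1] + curve[-length(grid)]) / 2 * diff(grid)) / 15
  expect_equal(pck_auc(e), trap, tolerance = 1e-3)
})

test_that("TSE vanishes for matched second derivatives and matches a closed form", {
  tt <- 120
  lin <- array(0, c(tt, 1, 3))
  lin[, 1, 1] <- seq_len(tt) * 0.5          # linear trajectory
  lin2 <- lin * 3 + 4                        # different slope and offset
  expect_equal(tse(lin, lin), 0)
  expect_equal(tse(lin, lin2), 0, tolerance = 1e-9)
  expect_error(tse(lin[1:2, , , drop = FALSE], lin[1:2, , , drop = FALSE]), "3 frames")
  # static prediction against a sinusoid: discrete second-difference oracle
  dt <- 1 / 60; A <- 2; f <- 1.5
  tv <- (0:(tt - 1)) * dt
  gt <- array(0, c(tt, 1, 3))
  gt[, 1, 2] <- A * sin(2 * pi * f * tv)
  pred <- array(0, c(tt, 1, 3))
  acc <- (gt[3:tt, 1, 2] - 2 * gt[2:(tt - 1), 1, 2] + gt[1:(tt - 2), 1, 2]) / dt^2
  expect_equal(tse(pred, gt), mean(abs(acc)) / 100, tolerance = 1e-12)
})

test_that("angular MAE averages geodesic errors with antipodal safety", {
  q <- array(0, c(10, 2, 4))
  for (j in 1:2) q[, j, ] <- random_unit_quats(10, seed = 50 + j)
  expect_equal(mae_deg(q, q), 0, tolerance = 1e-4)
  qneg <- -q
  expect_equal(mae_deg(qneg, q), 0, tolerance = 1e-4)
  rot10 <- quat_from_axis_angle(c(0, 0, 1), 10 * pi / 180)
  q2 <- q
  for (j in 1:2) q2[, j, ] <- quat_multiply(rot10, q[, j, ])
  expect_equal(mae_deg(q2, q), 10, tolerance = 1e-9)
})

test_that("frame-wise statistics use population sigma and CV", {
  s <- framewise_stats(c(4, 6))
  expect_equal(s$mean, 5)
  expect_equal(s$sigma, 1)
  expect_equal(s$cv, 0.2)
  s0 <- framewise_stats(rep(3, 10))
  expect_equal(s0$sigma, 0); expect_equal(s0$cv, 0)
  expect_error(framewise_stats(numeric(0)), "empty")
})

test_that("metrics are invariant to a common translation of both trajectories", {
  set.seed(55)
  p <- array(rnorm(30 * 4 * 3), c(30, 4, 3))
  g <- p + array(rnorm(360, sd = 0.5), c(30, 4, 3))
  shift <- array(rep(c(5, -3, 2), each = 30 * 4), c(30, 4, 3))
  expect_equal(mpjpe(p + shift, g + shift), mpjpe(p, g), tolerance = 1e-12)
  expect_equal(tse(p + shift, g + shift), tse(p, g), tolerance = 1e-9)
  e1 <- sqrt(apply((p - g)^2, c(1, 2), sum))
  expect_equal(pck_auc(e1), pck_auc(sqrt(apply(((p + shift) - (g + shift))^2, c(1, 2), sum))),
               tolerance = 1e-12)
})

test_that("the metrics report aggregates frame-wise and prints cleanly", {
  set.seed(56)
  n <- 40
  gt_q <- array(0, c(n, 4, 4)); pr_q <- array(0, c(n, 4, 4))
  for (j in 1:4) {
    gt_q[, j, ] <- random_unit_quats(n, seed = 60 + j)
    pr_q[, j, ] <- quat_multiply(quat_exp(matrix(rnorm(n * 3, 0, 0.05), n, 3)),
                                 gt_q[, j, ])
  }
  gt_p <- array(rnorm(n * 4 * 3, sd = 10), c(n, 4, 3))
  pr_p <- gt_p + array(rnorm(n * 12, sd = 1), c(n, 4, 3))
  rep <- metrics_report(pr_q, gt_q, pr_p, gt_p)
  expect_true(rep$pck5 >= 0 && rep$pck5 <= 100)
  expect_true(rep$pck_auc >= 0 && rep$pck_auc <= 1)
  expect_equal(rep$n_frames, n)
  expect_length(rep$per_joint_mpjpe, 4)
  expect_output(print(rep), "MPJPE")
})
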