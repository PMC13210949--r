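test_that("sanitization accepts clean streams, repairs short gaps, rejects long ones", {
  st <- static_stream(600)
  out <- sanitize_stream(st)
  expect_true(out$accepted)
  expect_equal(out$stream$w, st$w)
  expect_equal(out$stream$q, st$q, tolerance = 1e-12)

  # single-frame NaN interpolated at the midpoint
  st2 <- static_stream(100)
  st2$w[, 1, 1] <- seq(0, 0.99, by = 0.01)
  st2$w[50, 1, 1] <- NaN
  out2 <- sanitize_stream(st2)
  expect_true(out2$accepted)
  expect_equal(out2$stream$w[50, 1, 1], (0.48 + 0.50) / 2)

  # an infinity anywhere rejects the file
  st3 <- static_stream(100)
  st3$a[10, 2, 3] <- Inf
  out3 <- sanitize_stream(st3)
  expect_false(out3$accepted)
  expect_match(out3$report, "infinite")

  # a NaN run at max_gap rejects
  st4 <- static_stream(100)
  st4$w[40:42, 3, 2] <- NaN
  expect_false(sanitize_stream(st4, max_gap = 3)$accepted)

  st5 <- static_stream(100)
  st5$time[5] <- st5$time[7]
  expect_error(sanitize_stream(st5), "monotonic")
})

test_that("pooled normalization statistics share one (mu, sigma) per sensor-modality", {
  st <- static_stream(100)
  stats0 <- compute_norm_stats(list(st))
  expect_equal(stats0$mu_w, rep(0, 5))
  expect_equal(stats0$sigma_w, rep(1e-8, 5))  # sigma floor on constant input

  st$w[, 2, 1] <- 1; st$w[, 2, 2] <- 2; st$w[, 2, 3] <- 3
  s <- compute_norm_stats(list(st))
  expect_equal(s$mu_w[2], 2)
  # invariance to axis permutation
  st_p <- st
  st_p$w[, 2, ] <- st$w[, 2, c(3, 1, 2)]
  s_p <- compute_norm_stats(list(st_p))
  expect_equal(s$mu_w, s_p$mu_w)
  expect_equal(s$sigma_w, s_p$sigma_w)
  expect_error(compute_norm_stats(list()), "empty")
})

test_that("z-normalization clamps at five sigma", {
  expect_equal(znorm_clamp(2, mu = 2, sigma = 0.5), 0)
  expect_equal(znorm_clamp(2 + 10 * 0.5, mu = 2, sigma = 0.5), 5)
  expect_equal(znorm_clamp(2 - 2 * 0.5, mu = 2, sigma = 0.5), -2,
               tolerance = 1e-6)
  # for standard-normal input the clamped fraction matches the Gaussian tail
  set.seed(33)
  x <- rnorm(1e6)
  frac <- mean(abs(znorm_clamp(x, 0, 1)) >= 5)
  # two-sided tail mass beyond 5 sigma is ~5.7e-7; allow sampling noise
  expect_lte(frac, 1e-5)
})

test_that("feature assembly yields the 50-wide causal layout", {
  st <- static_stream(150)
  f <- assemble_features(st, unit_stats())
  expect_equal(ncol(f), 50)
  # static identity pose: quaternion blocks [1,0,0,0], inertial blocks -mu/sigma
  for (s in 1:5) {
    expect_equal(f[1, (s - 1) * 10 + 1:4], c(1, 0, 0, 0))
    expect_equal(f[1, (s - 1) * 10 + 5:10], rep(0, 6), tolerance = 1e-6)
  }
  # quaternion L2 normalization is idempotent
  f2 <- assemble_features(sanitize_stream(st)$stream, unit_stats())
  expect_equal(f, f2, tolerance = 1e-12)
  # layout audit: swapping two sensors relocates their blocks
  st_sw <- st
  st_sw$w[, 1, 1] <- 1
  f_sw <- assemble_features(st_sw, unit_stats())
  expect_equal(f_sw[1, 5], 1)
  expect_equal(f_sw[1, 15], 0)
  # causality: a frame's features do not depend on any later frame
  st_mut <- st
  st_mut$w[100, , ] <- 99
  f_mut <- assemble_features(st_mut, unit_stats())
  expect_equal(f_mut[1:99, ], f[1:99, ])
})

test_that("training targets carry the swing and recompose the relative rotation", {
  n <- 50
  truth <- list(
    q_proximal = array(0, c(n, 4, 4)), q_distal = array(0, c(n, 4, 4)),
    w = array(0, c(n, 4, 3)), a = array(0, c(n, 4, 3))
  )
  set.seed(12)
  for (j in 1:4) {
    truth$q_proximal[, j, ] <- random_unit_quats(n, seed = 40 + j)
    truth$q_distal[, j, ] <- random_unit_quats(n, seed = 50 + j)
  }
  tg <- make_training_targets(truth, unit_stats())
  expect_equal(dim(tg), c(n, 40))
  axes <- twist_axes_default()
  for (j in 1:4) {
    q_rel <- relative_rotation(truth$q_proximal[, j, ], truth$q_distal[, j, ])
    st <- swing_twist_batch(q_rel, axes[j, ])
    # swing (x) twist (x) distal recomposes the proximal orientation
    back <- quat_multiply(quat_multiply(tg[, (j - 1) * 10 + 1:4], st$twist),
                          truth$q_distal[, j, ])
    expect_lt(max(geodesic_error_deg(back, truth$q_proximal[, j, ])) * pi / 180,
              1e-7)
  }
  # proximal == distal gives identity swing; pure-axis rotation is all twist
  truth$q_distal <- truth$q_proximal
  tg_id <- make_training_targets(truth, unit_stats())
  for (j in 1:4) {
    expect_equal(tg_id[, (j - 1) * 10 + 1:4],
                 matrix(quat_identity(), n, 4, byrow = TRUE), tolerance = 1e-9)
  }
  ax_rot <- quat_from_axis_angle(c(1, 0, 0), 0.7)
  truth2 <- truth
  truth2$q_proximal[, 1, ] <- t(replicate(n, quat_multiply(ax_rot, truth$q_distal[1, 1, ])))
  truth2$q_distal[, 1, ] <- t(replicate(n, truth$q_distal[1, 1, ]))
  tg2 <- make_training_targets(truth2, unit_stats())
  expect_equal(tg2[, 1:4], matrix(quat_identity(), n, 4, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("sliding windows follow the count formula with zero look-ahead", {
  expect_equal(sliding_windows(120, L = 120, stride = 60), 120L)
  expect_equal(length(sliding_windows(240, L = 120, stride = 60)), 3)
  expect_equal(length(sliding_windows(1000, L = 120, stride = 30)),
               floor((1000 - 120) / 30) + 1)
  expect_warning(w <- sliding_windows(100, L = 120), "shorter")
  expect_length(w, 0)
  # window ends never exceed the series, so no future frame can be touched
  ends <- sliding_windows(500, L = 120, stride = 30)
  expect_true(all(ends <= 500) && all(ends >= 120))
})

test_that("hard-negative admissibility is a strict 0.1 rad/s criterion", {
  w <- array(0, c(100, 4, 3))
  expect_true(hard_negative_validity(w))
  w[50, 2, ] <- c(0.2, 0, 0)
  expect_false(hard_negative_validity(w))
  w[50, 2, ] <- c(0.1, 0, 0)   # exactly at the boundary: strict
  expect_false(hard_negative_validity(w))
  w[50, 2, ] <- c(0.0999, 0, 0)
  expect_true(hard_negative_validity(w))
})

test_that("batch mixing injects the rounded hard-negative count deterministically", {
  b <- mix_batches(1000, 100, batch_size = 64, r = 0.1, seed = 7)
  expect_true(all(vapply(b, function(x) length(x$hard), integer(1)) == 6))
  expect_true(all(vapply(b, function(x) length(x$adl), integer(1)) == 58))
  # r = 0: pure ADL batches
  b0 <- mix_batches(1000, 100, batch_size = 64, r = 0, seed = 7)
  expect_true(all(vapply(b0, function(x) length(x$hard), integer(1)) == 0))
  # minimum one hard negative when r > 0
  b1 <- mix_batches(1000, 100, batch_size = 8, r = 0.01, seed = 7)
  expect_true(all(vapply(b1, function(x) length(x$hard), integer(1)) == 1))
  # determinism per seed
  expect_identical(mix_batches(500, 50, seed = 42), mix_batches(500, 50, seed = 42))
  expect_false(identical(mix_batches(500, 50, seed = 42),
                         mix_batches(500, 50, seed = 43)))
  expect_error(mix_batches(10, 10, r = 1.5), "\\[0, 1\\]")
  # sampling without replacement within an epoch
  ba <- mix_batches(640, 100, batch_size = 64, r = 0.1, seed = 1)
  adl_all <- unlist(lapply(ba, `[[`, "adl"))
  expect_false(any(duplicated(adl_all)))
})

test_that("the CSV interchange format round-trips and the shipped example loads", {
  sim <- small_adl_sim(29, duration = 3)
  path <- tempfile(fileext = ".csv")
  write_stream_csv(sim$stream, path)
  back <- read_stream_csv(path)
  expect_equal(back$time, sim$stream$time)
  expect_equal(back$q, sim$stream$q, tolerance = 1e-12)
  expect_equal(back$w, sim$stream$w, tolerance = 1e-12)
  expect_equal(back$a, sim$stream$a, tolerance = 1e-12)
  unlink(path)

  shipped <- system.file("extdata", "example_stream.csv", package = "sparsekin")
  ex <- read_stream_csv(shipped)
  expect_equal(dim(ex$q)[2:3], c(5L, 4L))
  expect_true(sanitize_stream(ex)$accepted)
  expect_equal(ncol(assemble_features(ex, compute_norm_stats(list(ex)))), 50)
})
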