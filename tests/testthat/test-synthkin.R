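test_that("ADL generation is deterministic and respects its band limit", {
  s1 <- generate_adl_motion(duration = 10, seed = 5)
  s2 <- generate_adl_motion(duration = 10, seed = 5)
  expect_identical(s1$angles, s2$angles)
  s3 <- generate_adl_motion(duration = 10, seed = 6)
  expect_false(identical(s1$angles, s3$angles))
  # zero amplitude: static reference-pose stream
  s0 <- generate_adl_motion(duration = 5, seed = 5, amp_scale = 0)
  expect_true(all(vapply(s0$angles, function(a) all(a == 0), logical(1))))
  expect_error(generate_adl_motion(duration = 1), "at least 2")

  # proximal angular-velocity spectra carry essentially no power above 2 Hz
  sim <- simulate_imu_stream(s1, sim_config(seed = 9, duration = 2, mount_sigma = 0))
  w <- sim$truth$w[, 1, 1]
  n <- length(w)
  spec <- Mod(stats::fft(w - mean(w)))^2
  freq <- (seq_len(n) - 1) * 60 / n
  half <- freq <= 30
  hi <- freq > 2.5 & half
  expect_lt(sum(spec[hi]) / sum(spec[half]), 0.01)
})

test_that("isolation tasks stay admissible as hard negatives", {
  for (task in c("elbow_flexion", "pronation_supination", "knee_extension")) {
    script <- generate_isolation_task(task, freq = 1, seed = 3, duration = 10)
    sim <- simulate_imu_stream(script, sim_config(seed = 4, duration = 2))
    expect_true(hard_negative_validity(sim$truth$w),
                label = paste(task, "passes the 0.1 rad/s criterion"))
  }
  expect_error(generate_isolation_task("elbow_flexion", freq = 0.3), "0.5")
  expect_error(generate_isolation_task("elbow_flexion", freq = 2.5), "0.5")
})

test_that("knee extension keeps the hip pose constant while the shank oscillates", {
  script <- generate_isolation_task("knee_extension", freq = 1, seed = 7,
                                    duration = 10)
  sim <- simulate_imu_stream(script, sim_config(seed = 8, duration = 2))
  # thigh (proximal) orientation essentially constant relative to its start
  hip_dev <- geodesic_error_deg(
    sim$truth$q_proximal[, 3, ],
    matrix(quat_identity(), nrow(sim$truth$q_proximal), 4, byrow = TRUE))
  expect_lt(max(hip_dev), 2)
  # shank moves substantially
  shank_dev <- geodesic_error_deg(
    sim$truth$q_distal[, 3, ],
    matrix(quat_identity(), nrow(sim$truth$q_distal), 4, byrow = TRUE))
  expect_gt(max(shank_dev), 30)
})

test_that("distal angular-speed peak matches the sinusoid derivative", {
  freq <- 1.2
  script <- generate_isolation_task("elbow_flexion", freq = freq, seed = 9,
                                    duration = 12)
  sim <- simulate_imu_stream(script, sim_config(seed = 10, duration = 2,
                                                mount_sigma = 0))
  # left wrist gyro peak ~ 2 pi f A with A = 60 degrees
  speed <- sqrt(rowSums(sim$stream$w[, 1, ]^2))
  expected <- 2 * pi * freq * (60 * pi / 180)
  expect_equal(max(speed[120:600]), expected, tolerance = 0.05)
})

test_that("a static script yields constant orientations and zero inertial channels", {
  script <- generate_adl_motion(duration = 5, seed = 1, amp_scale = 0)
  sim <- simulate_imu_stream(script, sim_config(seed = 2, duration = 2,
                                                noise_sigma = 0))
  for (s in 1:5) {
    expect_equal(sim$stream$w[, s, ], matrix(0, 300, 3), tolerance = 1e-9)
    expect_equal(sim$stream$a[, s, ], matrix(0, 300, 3), tolerance = 1e-9)
    expect_equal(max(geodesic_error_deg(sim$stream$q[, s, ],
                                        sim$stream$q[rep(1, 300), s, ])), 0,
                 tolerance = 1e-9)
  }
})

test_that("simulated gyro matches the analytic derivative of a known rotation", {
  # single-axis sinusoidal elbow flexion: wrist gyro should track the
  # analytic angular rate of the flexion channel
  freq <- 1
  script <- generate_isolation_task("elbow_flexion", freq = freq, seed = 11,
                                    duration = 10)
  sim <- simulate_imu_stream(script, sim_config(seed = 12, duration = 2,
                                                mount_sigma = 0))
  t <- script$time
  amp <- 60 * pi / 180
  analytic <- abs(2 * pi * freq * amp * cos(2 * pi * freq * t))
  speed <- sqrt(rowSums(sim$stream$w[, 1, ]^2))
  idx <- 150:450   # post-ramp interior
  expect_lt(max(abs(speed[idx] - analytic[idx])), 0.05)
})

test_that("targets rebuilt from the calibrated stream match the stored truth", {
  sim <- small_adl_sim(25, duration = 10)
  stats <- unit_stats()
  tg <- make_training_targets(sim$truth, stats)
  # independently recompute the swing from the stored orientation pairs
  axes <- twist_axes_default()
  for (j in 1:4) {
    q_rel <- relative_rotation(sim$truth$q_proximal[, j, ],
                               sim$truth$q_distal[, j, ])
    sw <- swing_twist_batch(q_rel, axes[j, ])$swing
    expect_lt(max(geodesic_error_deg(tg[, (j - 1) * 10 + 1:4], sw)), 1e-4)
  }
  # and the distal orientations equal the calibrated wrist/ankle sensors
  cal <- calibrate_stream(sim$stream)
  for (j in 1:2) {
    expect_lt(max(geodesic_error_deg(cal$q[, j, ], sim$truth$q_distal[, j, ])),
              1e-4)
  }
})

test_that("boresight calibration removes the injected mounting offset", {
  sim <- small_adl_sim(26, duration = 5)
  cal <- calibrate_stream(sim$stream)
  for (s in 1:5) {
    expect_lt(geodesic_error_deg(cal$q[1, s, ], quat_identity()) * pi / 180,
              1e-6)
  }
})

test_that("integrating simulated angular velocity reproduces the orientations", {
  sim <- small_adl_sim(27, duration = 4)
  dt <- 1 / 60
  for (s in c(1, 3)) {
    q <- sim$stream$q[, s, ]
    w <- sim$stream$w[, s, ]
    qi <- q[1, ]
    n <- 120  # 2 s
    for (t in 1:(n - 1)) {
      # midpoint rule over the central-difference rates
      wm <- (w[t, ] + w[t + 1, ]) / 2
      qi <- quat_normalize(quat_multiply(quat_exp(wm * dt), qi))
    }
    expect_lt(geodesic_error_deg(qi, q[n, ]), 0.5)
  }
})

test_that("channel noise injection touches only inertial channels, deterministically", {
  sim <- small_adl_sim(28, duration = 5)
  st <- sim$stream
  n1 <- inject_noise_stream(st, 1, seed = 5)
  n2 <- inject_noise_stream(st, 1, seed = 5)
  expect_identical(n1$w, n2$w)
  expect_identical(n1$q, st$q)     # orientations bit-identical
  expect_identical(inject_noise_stream(st, 0, seed = 5), st)
  # empirical variance of the added noise close to sigma^2
  d <- as.vector(n1$w - st$w)
  expect_equal(stats::var(d), 1, tolerance = 0.05)

  # feature-space injection perturbs only the inertial columns
  f <- assemble_features(calibrate_stream(st), unit_stats())
  fn <- inject_noise(f, 0.5, seed = 6)
  qcols <- as.vector(vapply(1:5, function(s) (s - 1L) * 10L + 1:4, integer(4)))
  expect_identical(fn[, qcols], f[, qcols])
  expect_false(identical(fn[, 5], f[, 5]))
  expect_identical(inject_noise(f, 0, seed = 6), f)
})

test_that("ADL joint channels stay inside anatomical ranges after ramp-in", {
  script <- generate_adl_motion(duration = 30, seed = 13)
  post <- script$time > 1.5
  deg <- 180 / pi
  for (ch in c("l_elbow_flex", "r_elbow_flex", "l_knee_flex", "r_knee_flex")) {
    a <- script$angles[[ch]][post] * deg
    expect_true(all(a >= 5 & a <= 150), label = paste(ch, "within [5,150]"))
  }
  for (ch in grep("shoulder|hip", names(script$angles), value = TRUE)) {
    a <- script$angles[[ch]][post] * deg
    expect_true(all(a >= -45 & a <= 150), label = paste(ch, "within box"))
  }
})
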