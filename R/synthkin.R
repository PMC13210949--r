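#' Synthetic articulated motion and IMU stream generator
#'
#' A nine-segment skeleton (torso root, upper arms, forearms, thighs,
#' shanks) is driven by time-parameterized joint-angle channels.  Natural
#' ("ADL-like") motion is a band-limited sum of at most five random
#' sinusoids per channel (frequencies below 2 Hz, amplitudes inside the
#' anatomical ranges, cross-joint coupling through a shared phase pool),
#' ramped in smoothly from the initial reference pose.  Distal-isolation
#' hard-negative tasks oscillate one distal joint at a prescribed frequency
#' while every proximal joint stays still except for sub-threshold
#' micro-wander.  From a motion script, the IMU emulator derives per-sensor
#' orientations (with a constant mounting offset), angular velocity by
#' finite-differencing the orientation trajectory, and gravity-free linear
#' acceleration by double-differencing the sensor position, plus the
#' ground-truth proximal targets.
#'
#' @name synthkin
NULL

# joint-angle channel names of a motion script
.script_channels <- function() {
  c("torso_x", "torso_y", "torso_z",
    "l_shoulder_x", "l_shoulder_y", "l_shoulder_z",
    "r_shoulder_x", "r_shoulder_y", "r_shoulder_z",
    "l_elbow_flex", "l_forearm_twist", "r_elbow_flex", "r_forearm_twist",
    "l_hip_x", "l_hip_y", "l_hip_z", "r_hip_x", "r_hip_y", "r_hip_z",
    "l_knee_flex", "r_knee_flex")
}

# smooth ramp-in: 0 at t=0 with zero slope, 1 after ramp_s seconds
.ramp <- function(t, ramp_s = 1) {
  u <- pmin(t / ramp_s, 1)
  u * u * (3 - 2 * u)
}

#' Simulation configuration
#'
#' @param seed integer RNG seed
#' @param duration stream length in seconds
#' @param fs sample rate in Hz (default 60)
#' @param noise_sigma additive Gaussian channel noise s.d. applied to the
#'   physical angular-velocity and acceleration channels (default 0)
#' @param mount_sigma s.d. (radians) of the random per-sensor mounting
#'   offset rotation vector (default 0.05)
#' @param gravity gravitational acceleration, m/s^2 (the emitted linear
#'   acceleration is gravity-free; the value is kept for the alternative
#'   gravity-included convention)
#' @param gravity_mode `"free"` (default) or `"included"`
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 42L, duration = 60, fs = 60L, noise_sigma = 0,
                       mount_sigma = 0.05, gravity = 9.81,
                       gravity_mode = c("free", "included")) {
  stopifnot(noise_sigma >= 0, duration >= 2, fs > 0)
  structure(list(seed = as.integer(seed), duration = duration,
                 fs = as.integer(fs), noise_sigma = noise_sigma,
                 mount_sigma = mount_sigma, gravity = gravity,
                 gravity_mode = match.arg(gravity_mode)),
            class = "sim_config")
}

#' Generate a smooth ADL-like motion script
#'
#' Every channel is a ramped, band-limited sum of at most five random
#' sinusoids (frequencies below 2 Hz, amplitudes inside the channel's
#' anatomical range).  Within each limb the distal and proximal channels
#' share a common harmonic drive: natural movement is synergistic — elbow
#' flexion co-occurs with shoulder motion, knee flexion with hip motion —
#' and it is exactly this synergy that makes kinematic bleed-through a real
#' failure mode for a regressor trained on natural motion alone.
#' Deterministic per seed.
#'
#' @param duration seconds (>= 2)
#' @param seed integer seed
#' @param fs sample rate (Hz)
#' @param amp_scale global amplitude multiplier (0 gives a static reference
#'   pose stream)
#' @param coupling fraction of each proximal channel driven by its limb's
#'   shared harmonic drive (default 0.6)
#' @return a `motion_script` list: `time`, per-channel `angles` (radians),
#'   `label`, `fs`
#' @export
generate_adl_motion <- function(duration = 60, seed = 42L, fs = 60L,
                                amp_scale = 1, coupling = 0.6) {
  if (duration < 2) stop("duration must be at least 2 s")
  rng <- .seeded_rng(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  env <- .ramp(t)
  # unit-amplitude band-limited oscillation (sum |a| = 1 so |osc| <= 1)
  osc <- function() {
    k <- max(1L, as.integer(round(rng$runif(1, 2, 5))))
    f <- rng$runif(k, 0.1, 1.8)
    ph <- rng$runif(k, 0, 2 * pi)
    a <- rng$runif(k, 0.2, 1) / (1 + f)        # calmer high frequencies
    a <- a / sum(a)
    x <- numeric(length(t))
    for (i in seq_len(k)) x <- x + a[i] * sin(2 * pi * f[i] * t + ph[i])
    x
  }
  # one shared harmonic drive per limb (the within-limb synergy)
  drive <- list(l_arm = osc(), r_arm = osc(), l_leg = osc(), r_leg = osc())
  limb_of <- function(ch) {
    if (grepl("^l_(shoulder|elbow|forearm)", ch)) "l_arm"
    else if (grepl("^r_(shoulder|elbow|forearm)", ch)) "r_arm"
    else if (grepl("^l_(hip|knee)", ch)) "l_leg"
    else if (grepl("^r_(hip|knee)", ch)) "r_leg"
    else NA_character_
  }
  # per-channel amplitude budgets (radians)
  budget <- function(ch) {
    if (grepl("torso", ch)) 0.12
    else if (grepl("shoulder", ch)) 0.40
    else if (grepl("elbow_flex", ch)) 0.45
    else if (grepl("forearm", ch)) 0.40
    else if (grepl("hip", ch)) 0.35
    else 0.45                                   # knee
  }
  angles <- list()
  for (ch in .script_channels()) {
    b <- budget(ch) * amp_scale
    limb <- limb_of(ch)
    x <- if (is.na(limb)) {
      b * osc()
    } else {
      b * (coupling * drive[[limb]] + (1 - coupling) * osc())
    }
    base <- if (grepl("elbow_flex|knee_flex", ch)) {
      # hinge channels oscillate around mid-range so limits hold post-ramp
      (70 * pi / 180)
    } else 0
    angles[[ch]] <- env * (base * amp_scale + x)
  }
  structure(list(time = t, angles = angles, label = "adl", fs = fs),
            class = "motion_script")
}

#' Generate a distal-isolation hard-negative script
#'
#' The named distal joint oscillates at `freq` (0.5-2.0 Hz, ramped in)
#' while all proximal joints hold their pose with only micro-wander far
#' below the 0.1 rad/s admissibility threshold.  Tasks: `elbow_flexion`
#' (locked humerus, both elbows), `pronation_supination` (elbows held at
#' 90 degrees, forearm axial oscillation), `knee_extension` (seated: hips
#' held at 90 degrees flexion, both knees oscillate).
#'
#' @param task one of `"elbow_flexion"`, `"pronation_supination"`,
#'   `"knee_extension"`
#' @param freq oscillation frequency in Hz, must lie in `[0.5, 2.0]`
#' @param seed integer seed (micro-wander phases)
#' @param duration seconds
#' @param fs sample rate (Hz)
#' @return a `motion_script` with label `"hard_negative:<task>"`
#' @export
generate_isolation_task <- function(task = c("elbow_flexion",
                                             "pronation_supination",
                                             "knee_extension"),
                                    freq = 1, seed = 42L, duration = 30,
                                    fs = 60L) {
  task <- match.arg(task)
  if (freq < 0.5 || freq > 2.0) {
    stop("isolation-task frequency must lie in [0.5, 2.0] Hz")
  }
  rng <- .seeded_rng(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  env <- .ramp(t)
  angles <- stats::setNames(
    rep(list(numeric(length(t))), length(.script_channels())),
    .script_channels())
  # micro-wander on proximal channels: 0.008 rad at 0.2 Hz -> |omega| ~ 0.01 rad/s
  micro <- function() {
    ph <- rng$runif(1, 0, 2 * pi)
    env * 0.008 * sin(2 * pi * 0.2 * t + ph)
  }
  prox <- c("l_shoulder_x", "l_shoulder_y", "l_shoulder_z",
            "r_shoulder_x", "r_shoulder_y", "r_shoulder_z",
            "l_hip_x", "l_hip_y", "l_hip_z", "r_hip_x", "r_hip_y", "r_hip_z")
  for (ch in prox) angles[[ch]] <- micro()
  osc <- env * sin(2 * pi * freq * t)
  deg <- pi / 180
  if (task == "elbow_flexion") {
    angles$l_elbow_flex <- env * 75 * deg + 60 * deg * osc
    angles$r_elbow_flex <- env * 75 * deg - 60 * deg * osc
  } else if (task == "pronation_supination") {
    angles$l_elbow_flex <- env * 90 * deg
    angles$r_elbow_flex <- env * 90 * deg
    angles$l_forearm_twist <- 70 * deg * osc
    angles$r_forearm_twist <- -70 * deg * osc
  } else {
    # seated from the first frame: the hips hold 90 degrees (plus micro-
    # wander) for the whole capture, so proximal angular speed stays tiny
    angles$l_hip_x <- 90 * deg + angles$l_hip_x
    angles$r_hip_x <- 90 * deg + angles$r_hip_x
    angles$l_knee_flex <- env * 75 * deg + 60 * deg * osc
    angles$r_knee_flex <- env * 75 * deg - 60 * deg * osc
  }
  structure(list(time = t, angles = angles, label = paste0("hard_negative:", task),
                 fs = fs),
            class = "motion_script")
}

# per-segment world-frame motion quaternions (identity = reference pose)
.script_orientations <- function(script) {
  an <- script$angles
  tt <- length(script$time)
  rotvec <- function(x, y, z) quat_exp(cbind(x, y, z))
  hinge <- function(axis, ang) quat_exp(outer(ang, axis))
  torso <- rotvec(an$torso_x, an$torso_y, an$torso_z)
  l_ua <- quat_multiply(torso, rotvec(an$l_shoulder_x, an$l_shoulder_y, an$l_shoulder_z))
  r_ua <- quat_multiply(torso, rotvec(an$r_shoulder_x, an$r_shoulder_y, an$r_shoulder_z))
  # elbow flexion about z (mirrored), axial pronation about the arm axis x
  l_fa <- quat_multiply(l_ua, quat_multiply(hinge(c(0, 0, 1), an$l_elbow_flex),
                                            hinge(c(1, 0, 0), an$l_forearm_twist)))
  r_fa <- quat_multiply(r_ua, quat_multiply(hinge(c(0, 0, -1), an$r_elbow_flex),
                                            hinge(c(1, 0, 0), an$r_forearm_twist)))
  l_th <- quat_multiply(torso, rotvec(an$l_hip_x, an$l_hip_y, an$l_hip_z))
  r_th <- quat_multiply(torso, rotvec(an$r_hip_x, an$r_hip_y, an$r_hip_z))
  l_sh <- quat_multiply(l_th, hinge(c(1, 0, 0), an$l_knee_flex))
  r_sh <- quat_multiply(r_th, hinge(c(1, 0, 0), an$r_knee_flex))
  list(torso = torso, l_upper_arm = l_ua, r_upper_arm = r_ua,
       l_forearm = l_fa, r_forearm = r_fa, l_thigh = l_th, r_thigh = r_th,
       l_shank = l_sh, r_shank = r_sh)
}

# world positions (cm) of the joints needed by sensors and targets
.script_positions <- function(orients, skeleton = skeleton_default()) {
  sk <- skeleton
  len <- function(s) sk$length[sk$segment == s]
  dvec <- function(s) {
    i <- which(sk$segment == s)
    c(sk$dx[i], sk$dy[i], sk$dz[i])
  }
  tt <- nrow(orients$torso)
  rot <- function(q, s) quat_rotate(q, matrix(dvec(s) * len(s), tt, 3, byrow = TRUE))
  p_sh_l <- rot(orients$torso, "left_shoulder")
  p_sh_r <- rot(orients$torso, "right_shoulder")
  p_el_l <- p_sh_l + rot(orients$l_upper_arm, "left_upper_arm")
  p_el_r <- p_sh_r + rot(orients$r_upper_arm, "right_upper_arm")
  p_wr_l <- p_el_l + rot(orients$l_forearm, "left_forearm")
  p_wr_r <- p_el_r + rot(orients$r_forearm, "right_forearm")
  p_hip_l <- rot(orients$torso, "left_hip")
  p_hip_r <- rot(orients$torso, "right_hip")
  p_kn_l <- p_hip_l + rot(orients$l_thigh, "left_thigh")
  p_kn_r <- p_hip_r + rot(orients$r_thigh, "right_thigh")
  p_an_l <- p_kn_l + rot(orients$l_shank, "left_shank")
  p_an_r <- p_kn_r + rot(orients$r_shank, "right_shank")
  list(elbow_l = p_el_l, elbow_r = p_el_r, wrist_l = p_wr_l, wrist_r = p_wr_r,
       knee_l = p_kn_l, knee_r = p_kn_r, ankle_l = p_an_l, ankle_r = p_an_r,
       sternum = matrix(0, tt, 3))
}

# central-difference angular velocity (rad/s) of a quaternion trajectory
.quat_omega <- function(q, dt) {
  tt <- nrow(q)
  w <- matrix(0, tt, 3)
  if (tt >= 3) {
    w[2:(tt - 1), ] <- quat_log(
      quat_multiply(q[3:tt, , drop = FALSE],
                    quat_inverse(q[1:(tt - 2), , drop = FALSE]))) / (2 * dt)
  }
  if (tt >= 2) {
    w[1, ] <- quat_log(quat_multiply(q[2, ], quat_inverse(q[1, ]))) / dt
    w[tt, ] <- quat_log(quat_multiply(q[tt, ], quat_inverse(q[tt - 1, ]))) / dt
  }
  w
}

# second-difference linear acceleration (m/s^2) from positions in cm
.pos_accel <- function(p, dt) {
  tt <- nrow(p)
  a <- matrix(0, tt, 3)
  pm <- p / 100
  if (tt >= 3) {
    a[2:(tt - 1), ] <- (pm[3:tt, ] - 2 * pm[2:(tt - 1), ] + pm[1:(tt - 2), ]) / dt^2
    a[1, ] <- a[2, ]; a[tt, ] <- a[tt - 1, ]
  }
  a
}

#' Simulate an IMU stream and its ground truth from a motion script
#'
#' Sensor orientations compose the segment's world rotation with a constant
#' random mounting offset (left-multiplied frame offset, removable exactly
#' by boresight calibration); angular velocity is the central finite
#' difference of the orientation trajectory mapped through the quaternion
#' log; linear acceleration is the discrete second derivative of the sensor
#' position, gravity-free by default.  Ground truth carries the four
#' proximal/distal orientation pairs expressed relative to the capture's
#' initial pose (the frame a boresight-calibrated stream lives in), the
#' proximal angular velocities, and the proximal endpoint accelerations.
#'
#' @param script a `motion_script`
#' @param config a [sim_config()]
#' @param skeleton evaluation skeleton (segment lengths in cm)
#' @return list with `stream` (raw `imu_stream` including mounting offsets),
#'   `truth` (list `q_proximal`, `q_distal` T x 4 x 4; `w`, `a` T x 4 x 3;
#'   `q_torso`; `positions` of the proximal endpoints), and `label`
#' @export
simulate_imu_stream <- function(script, config = sim_config(),
                                skeleton = skeleton_default()) {
  rng <- .seeded_rng(config$seed)
  dt <- 1 / config$fs
  orients <- .script_orientations(script)
  pos <- .script_positions(orients, skeleton)
  tt <- length(script$time)

  sensor_segs <- list(left_wrist = "l_forearm", right_wrist = "r_forearm",
                      left_ankle = "l_shank", right_ankle = "r_shank",
                      torso = "torso")
  sensor_pos <- list(left_wrist = pos$wrist_l, right_wrist = pos$wrist_r,
                     left_ankle = pos$ankle_l, right_ankle = pos$ankle_r,
                     torso = pos$sternum)
  q <- array(0, c(tt, 5, 4)); w <- array(0, c(tt, 5, 3)); a <- array(0, c(tt, 5, 3))
  for (s in seq_along(sensor_names())) {
    seg <- orients[[sensor_segs[[sensor_names()[s]]]]]
    mount <- quat_exp(rng$rnorm(3, 0, config$mount_sigma))
    q_raw <- quat_multiply(mount, seg)
    q[, s, ] <- q_raw
    w[, s, ] <- .quat_omega(q_raw, dt)
    acc <- .pos_accel(sensor_pos[[sensor_names()[s]]], dt)
    if (config$gravity_mode == "included") {
      acc[, 2] <- acc[, 2] + config$gravity
    }
    a[, s, ] <- acc
  }
  if (config$noise_sigma > 0) {
    w <- w + array(rng$rnorm(length(w), 0, config$noise_sigma), dim(w))
    a <- a + array(rng$rnorm(length(a), 0, config$noise_sigma), dim(a))
  }
  stream <- imu_stream(script$time, q, w, a)

  # ground truth relative to the initial (calibration) pose
  cal <- function(qm) quat_multiply(quat_inverse(qm[1, ]), qm)
  pairs <- list(c("l_upper_arm", "l_forearm"), c("r_upper_arm", "r_forearm"),
                c("l_thigh", "l_shank"), c("r_thigh", "r_shank"))
  prox_pos <- list(pos$elbow_l, pos$elbow_r, pos$knee_l, pos$knee_r)
  q_p <- array(0, c(tt, 4, 4)); q_d <- array(0, c(tt, 4, 4))
  w_p <- array(0, c(tt, 4, 3)); a_p <- array(0, c(tt, 4, 3))
  positions <- array(0, c(tt, 4, 3))
  for (j in 1:4) {
    qp <- cal(orients[[pairs[[j]][1]]])
    qd <- cal(orients[[pairs[[j]][2]]])
    q_p[, j, ] <- qp; q_d[, j, ] <- qd
    w_p[, j, ] <- .quat_omega(qp, dt)
    a_p[, j, ] <- .pos_accel(prox_pos[[j]], dt)
    positions[, j, ] <- prox_pos[[j]]
  }
  list(stream = stream,
       truth = list(q_proximal = q_p, q_distal = q_d, w = w_p, a = a_p,
                    q_torso = cal(orients$torso), positions = positions),
       label = script$label)
}

#' Boresight-calibrate a simulated stream
#'
#' Left-multiplies every sensor's orientation trajectory by the inverse of
#' its first frame, the stream-level analogue of [boresight_calibrate()];
#' inertial channels are unchanged.
#'
#' @param stream an `imu_stream`
#' @return calibrated `imu_stream` (identity orientations at the first
#'   frame)
#' @export
calibrate_stream <- function(stream) {
  q <- stream$q
  for (s in 1:5) {
    off <- boresight_offset(q[1, s, ])
    q[, s, ] <- boresight_calibrate(q[, s, , drop = TRUE], off)
  }
  imu_stream(stream$time, q, stream$w, stream$a)
}

#' Inject Gaussian channel noise into a feature matrix
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to the normalized angular-velocity and
#' acceleration columns of an assembled T x 50 feature matrix; quaternion
#' columns are untouched.  Deterministic per seed.
#'
#' @param features T x 50 feature matrix from [assemble_features()]
#' @param sigma noise standard deviation in normalized-feature units
#' @param seed integer seed
#' @return perturbed copy of `features`
#' @export
inject_noise <- function(features, sigma, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0) return(features)
  rng <- .seeded_rng(seed)
  cols <- as.vector(vapply(1:5, function(s) (s - 1L) * 10L + 5:10, integer(6)))
  noise <- matrix(rng$rnorm(nrow(features) * length(cols), 0, sigma),
                  nrow(features), length(cols))
  features[, cols] <- features[, cols] + noise
  features
}

#' Inject Gaussian channel noise into a physical-unit stream
#'
#' @param stream an `imu_stream`
#' @param sigma noise s.d. in physical units (rad/s and m/s^2)
#' @param seed integer seed
#' @return perturbed `imu_stream` (orientations untouched)
#' @export
inject_noise_stream <- function(stream, sigma, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0) return(stream)
  rng <- .seeded_rng(seed)
  w <- stream$w + array(rng$rnorm(length(stream$w), 0, sigma), dim(stream$w))
  a <- stream$a + array(rng$rnorm(length(stream$a), 0, sigma), dim(stream$a))
  imu_stream(stream$time, stream$q, w, a)
}
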