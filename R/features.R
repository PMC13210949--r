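#' Stream containers, sanitization, normalization and windowing
#'
#' A sensor stream is a list of class `imu_stream` holding `time` (seconds,
#' length T), and three arrays indexed `[frame, sensor, channel]`: `q`
#' (T x 5 x 4 unit quaternions), `w` (T x 5 x 3 angular velocity, rad/s) and
#' `a` (T x 5 x 3 linear acceleration, m/s^2).  Sensor order is fixed:
#' left wrist, right wrist, left ankle, right ankle, torso.  The feature
#' layout per frame is five 10-dim sensor blocks
#' `(qw, qx, qy, qz, wx, wy, wz, ax, ay, az)` concatenated in that order,
#' 50 columns in total.
#'
#' @name features
NULL

#' Canonical sensor order
#' @return character vector of the five instrumented segments
#' @export
sensor_names <- function() {
  c("left_wrist", "right_wrist", "left_ankle", "right_ankle", "torso")
}

#' Canonical predicted-joint order
#' @return character vector of the four uninstrumented proximal joints
#' @export
joint_names <- function() {
  c("left_upper_arm", "right_upper_arm", "left_upper_leg", "right_upper_leg")
}

#' Construct an IMU stream object
#' @param time numeric vector of timestamps (seconds)
#' @param q T x 5 x 4 orientation array
#' @param w T x 5 x 3 angular-velocity array (rad/s)
#' @param a T x 5 x 3 linear-acceleration array (m/s^2)
#' @return an `imu_stream` list
#' @export
imu_stream <- function(time, q, w, a) {
  stopifnot(length(dim(q)) == 3L, dim(q)[2] == 5L, dim(q)[3] == 4L,
            all(dim(w) == c(length(time), 5L, 3L)),
            all(dim(a) == c(length(time), 5L, 3L)),
            dim(q)[1] == length(time))
  structure(list(time = time, q = q, w = w, a = a), class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d frames, %.2f s, 5 sensors\n",
              length(x$time), diff(range(x$time))))
  invisible(x)
}

#' Write a stream to the long CSV interchange format
#'
#' One row per sensor per tick with header
#' `time,sensor,qw,qx,qy,qz,wx,wy,wz,ax,ay,az`.
#'
#' @param stream an `imu_stream`
#' @param path output file path
#' @export
write_stream_csv <- function(stream, path) {
  n <- length(stream$time)
  rows <- do.call(rbind, lapply(seq_len(5L), function(s) {
    data.frame(
      time = stream$time, sensor = sensor_names()[s],
      qw = stream$q[, s, 1], qx = stream$q[, s, 2],
      qy = stream$q[, s, 3], qz = stream$q[, s, 4],
      wx = stream$w[, s, 1], wy = stream$w[, s, 2], wz = stream$w[, s, 3],
      ax = stream$a[, s, 1], ay = stream$a[, s, 2], az = stream$a[, s, 3]
    )
  }))
  rows <- rows[order(rows$time, match(rows$sensor, sensor_names())), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a stream from the long CSV interchange format
#' @param path CSV file path
#' @return an `imu_stream`
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "sensor", "qw", "qx", "qy", "qz",
            "wx", "wy", "wz", "ax", "ay", "az")
  if (!all(need %in% names(df))) stop("stream CSV missing required columns")
  times <- sort(unique(df$time))
  tt <- length(times)
  q <- array(NA_real_, c(tt, 5, 4))
  w <- array(NA_real_, c(tt, 5, 3))
  a <- array(NA_real_, c(tt, 5, 3))
  ti <- match(df$time, times)
  si <- match(df$sensor, sensor_names())
  if (anyNA(si)) stop("unknown sensor name in stream CSV")
  for (k in seq_len(nrow(df))) {
    q[ti[k], si[k], ] <- as.numeric(df[k, c("qw", "qx", "qy", "qz")])
    w[ti[k], si[k], ] <- as.numeric(df[k, c("wx", "wy", "wz")])
    a[ti[k], si[k], ] <- as.numeric(df[k, c("ax", "ay", "az")])
  }
  imu_stream(times, q, w, a)
}

# linear interpolation over short gaps in one channel vector; returns NULL
# when a gap exceeds max_gap or a boundary frame is missing
.fill_gaps <- function(x, max_gap) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (r$lengths[i] >= max_gap) return(NULL)
    lo <- starts[i] - 1L; hi <- ends[i] + 1L
    if (lo < 1L || hi > length(x)) return(NULL)
    x[starts[i]:ends[i]] <- x[lo] +
      (x[hi] - x[lo]) * (seq_len(r$lengths[i])) / (r$lengths[i] + 1L)
  }
  x
}

#' Sanitize a raw stream
#'
#' Checks timestamp monotonicity, interpolates isolated NaN gaps shorter than
#' `max_gap` consecutive frames (normalized linear interpolation for
#' quaternion channels, linear for inertial channels), and rejects files with
#' infinities or longer NaN runs, which would destabilize training gradients.
#'
#' @param stream an `imu_stream`
#' @param max_gap longest interpolatable NaN run, in frames (default 3)
#' @return list with `accepted` (logical), the repaired `stream` (or `NULL`),
#'   and a human-readable `report`
#' @export
sanitize_stream <- function(stream, max_gap = 3L) {
  if (is.unsorted(stream$time, strictly = TRUE)) {
    stop("non-monotonic timestamps in stream")
  }
  if (any(is.infinite(stream$q)) || any(is.infinite(stream$w)) ||
      any(is.infinite(stream$a))) {
    return(list(accepted = FALSE, stream = NULL,
                report = "stream contains infinite values"))
  }
  q <- stream$q; w <- stream$w; a <- stream$a
  for (s in 1:5) {
    for (c3 in 1:3) {
      for (nm in c("w", "a")) {
        x <- if (nm == "w") w[, s, c3] else a[, s, c3]
        filled <- .fill_gaps(x, max_gap)
        if (is.null(filled)) {
          return(list(accepted = FALSE, stream = NULL,
                      report = sprintf("NaN run >= %d frames in sensor %s", max_gap,
                                       sensor_names()[s])))
        }
        if (nm == "w") w[, s, c3] <- filled else a[, s, c3] <- filled
      }
    }
    for (c4 in 1:4) {
      filled <- .fill_gaps(q[, s, c4], max_gap)
      if (is.null(filled)) {
        return(list(accepted = FALSE, stream = NULL,
                    report = sprintf("NaN run >= %d frames in sensor %s", max_gap,
                                     sensor_names()[s])))
      }
      q[, s, c4] <- filled
    }
    # renormalize interpolated quaternions (normalized linear interpolation)
    qs <- q[, s, , drop = TRUE]
    q[, s, ] <- quat_normalize(qs)
  }
  list(accepted = TRUE, stream = imu_stream(stream$time, q, w, a),
       report = "ok")
}

#' Pooled normalization statistics
#'
#' One scalar `(mu, sigma)` pair per sensor and per inertial modality,
#' pooling all three spatial axes and all frames of the training streams so
#' the relative directional structure of each 3-vector is preserved.
#' Quaternion channels are never z-scored (they stay on the unit sphere).
#' Target statistics for the proximal joints are computed the same way from
#' the ground-truth tables when supplied.
#'
#' @param streams list of sanitized `imu_stream`s (the training partition)
#' @param targets optional list of ground-truth target lists, each with
#'   `w` and `a` arrays `[frame, joint, axis]`, to fit target statistics
#' @param sigma_floor lower bound for sigma (default 1e-8)
#' @return a `norm_stats` list with per-sensor `mu_w`, `sigma_w`, `mu_a`,
#'   `sigma_a`, and per-joint `tgt_mu_w`, `tgt_sigma_w`, `tgt_mu_a`,
#'   `tgt_sigma_a`
#' @export
compute_norm_stats <- function(streams, targets = NULL, sigma_floor = 1e-8) {
  if (length(streams) == 0L) stop("empty training partition")
  pool_sd <- function(x) max(stats::sd(x) * sqrt((length(x) - 1) / length(x)),
                             sigma_floor)
  mu_w <- sigma_w <- mu_a <- sigma_a <- numeric(5)
  for (s in 1:5) {
    ws <- unlist(lapply(streams, function(st) st$w[, s, ]))
    as <- unlist(lapply(streams, function(st) st$a[, s, ]))
    mu_w[s] <- mean(ws); sigma_w[s] <- pool_sd(ws)
    mu_a[s] <- mean(as); sigma_a[s] <- pool_sd(as)
  }
  out <- list(mu_w = mu_w, sigma_w = sigma_w, mu_a = mu_a, sigma_a = sigma_a)
  if (!is.null(targets)) {
    nj <- dim(targets[[1]]$w)[2]
    out$tgt_mu_w <- out$tgt_sigma_w <- numeric(nj)
    out$tgt_mu_a <- out$tgt_sigma_a <- numeric(nj)
    for (j in seq_len(nj)) {
      ws <- unlist(lapply(targets, function(tg) tg$w[, j, ]))
      as <- unlist(lapply(targets, function(tg) tg$a[, j, ]))
      out$tgt_mu_w[j] <- mean(ws); out$tgt_sigma_w[j] <- pool_sd(ws)
      out$tgt_mu_a[j] <- mean(as); out$tgt_sigma_a[j] <- pool_sd(as)
    }
  }
  structure(out, class = "norm_stats")
}

#' Z-normalize with outlier clamping
#'
#' `clamp((x - mu) / (sigma + eps), -bound, bound)`.  The default +/-5 sigma
#' bound retains rare but biomechanically valid high-velocity motion while
#' discarding non-biological transients.
#'
#' @param x numeric input (any shape)
#' @param mu,sigma scalar statistics
#' @param bound clamp bound in sigma units (default 5)
#' @param eps numerical-stability constant (default 1e-8)
#' @return normalized values, same shape as `x`
#' @export
znorm_clamp <- function(x, mu, sigma, bound = 5, eps = 1e-8) {
  pmin(pmax((x - mu) / (sigma + eps), -bound), bound)
}

#' Invert the z-normalization (without the clamp)
#' @inheritParams znorm_clamp
#' @return de-normalized values
#' @export
znorm_invert <- function(x, mu, sigma, eps = 1e-8) {
  x * (sigma + eps) + mu
}

#' Assemble the T x 50 feature matrix for a stream
#'
#' Quaternion blocks are L2-normalized (idempotent); angular velocity and
#' linear acceleration are z-normalized per sensor with the +/-5 sigma clamp.
#' Only the frame's own data enters its row, so features are strictly causal.
#'
#' @param stream a sanitized `imu_stream`
#' @param stats a `norm_stats` object fit on the training partition
#' @return numeric matrix with `length(stream$time)` rows and 50 columns
#' @export
assemble_features <- function(stream, stats) {
  tt <- length(stream$time)
  out <- matrix(0, tt, 50)
  for (s in 1:5) {
    base <- (s - 1L) * 10L
    out[, base + 1:4] <- quat_normalize(stream$q[, s, , drop = TRUE])
    out[, base + 5:7] <- znorm_clamp(stream$w[, s, , drop = TRUE],
                                     stats$mu_w[s], stats$sigma_w[s])
    out[, base + 8:10] <- znorm_clamp(stream$a[, s, , drop = TRUE],
                                      stats$mu_a[s], stats$sigma_a[s])
  }
  out
}

#' Build the 40-dim training target table for a stream
#'
#' Per joint, the target is the swing component of the proximal-relative-to-
#' distal rotation (twist about the limb's anatomical long axis removed),
#' followed by the proximal angular velocity and linear acceleration
#' z-normalized with the per-joint target statistics and clamped at +/-5
#' sigma.  The default twist axes follow the T-pose limb directions: the
#' horizontal x axis for the arms and the vertical y axis for the legs
#' (with a fixed x axis, knee articulation would be classified as axial
#' twist and stripped from the leg targets).
#'
#' @param truth ground-truth list with arrays `q_proximal` (T x J x 4),
#'   `q_distal` (T x J x 4), `w` (T x J x 3), `a` (T x J x 3)
#' @param stats a `norm_stats` object carrying target statistics
#' @param axes J x 3 matrix of per-joint twist axes
#' @return numeric matrix T x (10 * J), joint blocks in [joint_names()] order
#' @export
make_training_targets <- function(truth, stats, axes = twist_axes_default()) {
  tt <- dim(truth$q_proximal)[1]
  nj <- dim(truth$q_proximal)[2]
  out <- matrix(0, tt, 10L * nj)
  for (j in seq_len(nj)) {
    base <- (j - 1L) * 10L
    q_rel <- relative_rotation(truth$q_proximal[, j, , drop = TRUE],
                               truth$q_distal[, j, , drop = TRUE])
    st <- swing_twist_batch(q_rel, axis = axes[j, ])
    out[, base + 1:4] <- quat_canonicalize(st$swing)
    out[, base + 5:7] <- znorm_clamp(truth$w[, j, , drop = TRUE],
                                     stats$tgt_mu_w[j], stats$tgt_sigma_w[j])
    out[, base + 8:10] <- znorm_clamp(truth$a[, j, , drop = TRUE],
                                      stats$tgt_mu_a[j], stats$tgt_sigma_a[j])
  }
  out
}

#' Default anatomical twist axes per predicted joint
#'
#' Arms twist about the T-pose horizontal limb axis (x); legs about the
#' vertical limb axis (y).
#'
#' @return 4 x 3 matrix, rows in [joint_names()] order
#' @export
twist_axes_default <- function() {
  rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
}

#' Sliding-window index table
#'
#' Windows cover frames `[end - L + 1, end]`; the target is taken at the
#' window's final frame, so the mapping has zero look-ahead.  Window count is
#' `floor((T - L) / stride) + 1`.
#'
#' @param n_frames series length T
#' @param L window length in frames (default 120, i.e. 2.0 s at 60 Hz)
#' @param stride hop between window ends in frames (default 30)
#' @return integer vector of window end frames (empty, with a warning, when
#'   the series is shorter than `L`)
#' @export
sliding_windows <- function(n_frames, L = 120L, stride = 30L) {
  if (n_frames < L) {
    warning("series shorter than one window; no windows produced")
    return(integer(0))
  }
  seq.int(L, n_frames, by = stride)
}

#' Hard-negative validity of a proximal angular-velocity record
#'
#' A distal-isolation recording is admissible as a hard negative only when
#' every proximal joint stays essentially still: the angular speed
#' `||omega||` must stay strictly below `tol` rad/s at every frame.
#'
#' @param w_proximal array `[frame, joint, axis]` of proximal angular
#'   velocities in rad/s
#' @param tol strict threshold in rad/s (default 0.1)
#' @return `TRUE` iff all frames and joints satisfy the criterion
#' @export
hard_negative_validity <- function(w_proximal, tol = 0.1) {
  speed <- sqrt(apply(w_proximal^2, c(1, 2), sum))
  all(speed < tol)
}

#' Mixed ADL / hard-negative batch schedule
#'
#' Builds one epoch of batches where each batch holds
#' `round(r * batch_size)` hard-negative windows (at least 1 when `r > 0`;
#' round-half-to-even) and the rest natural-motion windows, both sampled
#' without replacement within the epoch and reshuffled per epoch from the
#' run seed.
#'
#' @param n_adl,n_hard pool sizes (window counts)
#' @param batch_size windows per batch (default 64)
#' @param r hard-negative fraction in `[0, 1]` (default 0.1)
#' @param seed integer seed for the epoch shuffle
#' @return list of batches; each batch is a list with integer vectors `adl`
#'   and `hard` indexing into the respective pools
#' @export
mix_batches <- function(n_adl, n_hard, batch_size = 64L, r = 0.1, seed = 42L) {
  if (r < 0 || r > 1) stop("hard-negative ratio r must lie in [0, 1]")
  n_hard_per <- if (r > 0) max(1L, as.integer(round(r * batch_size))) else 0L
  if (r > 0 && n_hard == 0L) stop("hard-negative pool empty while r > 0")
  n_adl_per <- batch_size - n_hard_per
  rng <- .seeded_rng(seed)
  adl_order <- rng$sample(n_adl)
  hard_order <- if (n_hard > 0L) rng$sample(n_hard) else integer(0)
  n_batches <- max(1L, n_adl %/% n_adl_per)
  batches <- vector("list", n_batches)
  hp <- 1L
  for (b in seq_len(n_batches)) {
    adl_idx <- adl_order[((b - 1L) * n_adl_per + 1L):min(b * n_adl_per, n_adl)]
    if (n_hard_per > 0L) {
      if (hp + n_hard_per - 1L > n_hard) {            # rewind the smaller pool
        hard_order <- rng$sample(n_hard)
        hp <- 1L
      }
      hard_idx <- hard_order[hp:(hp + n_hard_per - 1L)]
      hp <- hp + n_hard_per
    } else {
      hard_idx <- integer(0)
    }
    batches[[b]] <- list(adl = adl_idx, hard = hard_idx)
  }
  batches
}

# Self-contained RNG so batch schedules and weight init never disturb (or
# depend on) the caller's .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    sample = function(n, size = n) with_state(function() sample.int(n, size)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd))
  )
}
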