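#' Training, evaluation and streaming inference
#'
#' The pipeline turns simulated (or recorded) sensor streams into
#' sliding-window datasets, trains the attention regressor with AdamW under
#' the physics-informed multi-task loss and hard-negative batch mixing,
#' evaluates checkpoints with the root-relative metric suite (optionally
#' after joint-limit clamping and Kalman smoothing), replays streams
#' through a FIFO buffer for causal frame-by-frame inference, and sweeps
#' additive channel noise to chart degradation.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' Defaults mirror the full-scale training recipe: AdamW, learning rate
#' 1e-4, batch 64, 25 epochs with early stopping (patience 10) on the
#' validation multi-task loss, seed 42, window L = 120, hard-negative ratio
#' 0.1.  Desk-scale studies override `lr`, `epochs` and the model size.
#'
#' @param lr learning rate
#' @param batch_size windows per batch
#' @param epochs maximum epochs
#' @param patience early-stopping patience (epochs without validation
#'   improvement)
#' @param seed run seed (weights, shuffles, dropout)
#' @param r hard-negative fraction per batch
#' @param L window length (frames)
#' @param stride training window stride (frames)
#' @param weight_decay decoupled weight decay
#' @param weights [loss_weights()]
#' @param vel_scope `"all"` or `"hardneg"` (rows the velocity loss sees)
#' @return a `run_config` list
#' @export
run_config <- function(lr = 1e-4, batch_size = 64L, epochs = 25L,
                       patience = 10L, seed = 42L, r = 0.1, L = 120L,
                       stride = 30L, weight_decay = 0.01,
                       weights = loss_weights(),
                       vel_scope = c("all", "hardneg")) {
  stopifnot(lr > 0, batch_size > 0, epochs > 0, patience > 0, r >= 0, r <= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), r = r, L = as.integer(L),
                 stride = as.integer(stride), weight_decay = weight_decay,
                 weights = weights, vel_scope = match.arg(vel_scope)),
            class = "run_config")
}

#' Build a windowed dataset from simulated captures
#'
#' Calibrates and sanitizes each stream, fits pooled normalization
#' statistics on the supplied captures when `stats` is `NULL` (training
#' partitions only — evaluation partitions must reuse frozen training
#' statistics), assembles the T x 50 feature and T x 40 target tables, and
#' indexes sliding windows.
#'
#' @param sims list of [simulate_imu_stream()] results
#' @param stats frozen `norm_stats` or `NULL` to fit from `sims`
#' @param L window length (frames)
#' @param stride window stride (frames)
#' @return a `window_dataset` list: `features`, `targets`, `truths`,
#'   `labels`, `windows` (data frame `stream`, `end`, `hard`), `stats`
#' @export
build_dataset <- function(sims, stats = NULL, L = 120L, stride = 30L) {
  streams <- lapply(sims, function(s) {
    san <- sanitize_stream(calibrate_stream(s$stream))
    if (!san$accepted) stop("stream rejected during sanitization: ", san$report)
    san$stream
  })
  truths <- lapply(sims, `[[`, "truth")
  labels <- vapply(sims, `[[`, character(1), "label")
  if (is.null(stats)) stats <- compute_norm_stats(streams, truths)
  features <- lapply(streams, assemble_features, stats = stats)
  targets <- lapply(truths, make_training_targets, stats = stats)
  win <- do.call(rbind, lapply(seq_along(sims), function(i) {
    ends <- sliding_windows(nrow(features[[i]]), L = L, stride = stride)
    if (!length(ends)) return(NULL)
    data.frame(stream = i, end = ends,
               hard = grepl("^hard_negative", labels[i]))
  }))
  structure(list(features = features, targets = targets, truths = truths,
                 labels = labels, windows = win, stats = stats, L = L),
            class = "window_dataset")
}

# materialize a batch pre-flattened for the model: M0 [(B*L) x 50], Y [B x 40]
.gather_batch <- function(ds, rows) {
  L <- ds$L
  B <- length(rows)
  M0 <- matrix(0, B * L, 50L)
  Y <- matrix(0, B, 40L)
  st <- ds$windows$stream[rows]
  en <- ds$windows$end[rows]
  for (i in seq_len(B)) {
    M0[((i - 1L) * L + 1L):(i * L), ] <-
      ds$features[[st[i]]][(en[i] - L + 1L):en[i], ]
    Y[i, ] <- ds$targets[[st[i]]][en[i], ]
  }
  list(X = list(M0 = M0, B = B), Y = Y, hard = ds$windows$hard[rows])
}

.adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamw_update <- function(opt, params, grads, lr, wd, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step - lr * wd * params[[nm]]
  }
  list(opt = opt, params = params)
}

# mean multi-task loss over a dataset (forward only, eval mode)
.dataset_loss <- function(params, config, ds, run, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(ds$windows))
  tot <- 0; n <- 0
  for (start in seq(1, length(rows), by = run$batch_size)) {
    idx <- rows[start:min(start + run$batch_size - 1L, length(rows))]
    b <- .gather_batch(ds, idx)
    fw <- model_forward(params, b$X, config, training = FALSE)
    l <- total_loss(fw$pred, b$Y, run$weights, hard = b$hard,
                    vel_scope = run$vel_scope)
    tot <- tot + l$total * length(idx)
    n <- n + length(idx)
  }
  tot / n
}

#' Train the attention regressor
#'
#' Runs AdamW over mixed ADL / hard-negative batches, logs per-epoch
#' training and validation loss, retains the best-validation weights, and
#' stops early when validation stops improving.  Fully determined by
#' `run$seed` (weight init, epoch shuffles, dropout masks).
#'
#' @param ds_train,ds_val `window_dataset`s sharing the training statistics
#' @param config a [model_config()]
#' @param run a [run_config()]
#' @param verbose print per-epoch progress
#' @return a checkpoint list: `params`, `config`, `stats`, `run`, `history`
#'   (data frame epoch/train_loss/val_loss), `best_epoch`
#' @export
train_model <- function(ds_train, ds_val, config = model_config_small(),
                        run = run_config(), verbose = FALSE) {
  adl_rows <- which(!ds_train$windows$hard)
  hard_rows <- which(ds_train$windows$hard)
  if (!length(adl_rows)) stop("training partition has no ADL windows")
  params <- model_init(config, seed = run$seed)
  opt <- .adamw_init(params)
  drop_rng <- .seeded_rng(run$seed + 1L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(run$epochs)) {
    r_eff <- if (length(hard_rows)) run$r else 0
    sched <- mix_batches(length(adl_rows), length(hard_rows),
                         batch_size = run$batch_size, r = r_eff,
                         seed = run$seed + 100L * epoch)
    ep_loss <- 0; ep_n <- 0
    for (b in sched) {
      rows <- c(adl_rows[b$adl], hard_rows[b$hard])
      bt <- .gather_batch(ds_train, rows)
      fw <- model_forward(params, bt$X, config, training = TRUE, rng = drop_rng)
      l <- total_loss(fw$pred, bt$Y, run$weights, hard = bt$hard,
                      vel_scope = run$vel_scope, grad = TRUE)
      grads <- model_backward(params, fw$cache, l$grad, config)
      upd <- .adamw_update(opt, params, grads, run$lr, run$weight_decay)
      opt <- upd$opt; params <- upd$params
      ep_loss <- ep_loss + l$total * length(rows); ep_n <- ep_n + length(rows)
    }
    val <- .dataset_loss(params, config, ds_val, run)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = val))
    if (verbose) {
      message(sprintf("epoch %d | train %.5f | val %.5f", epoch,
                      ep_loss / ep_n, val))
    }
    if (val < best$val - 1e-9) {
      best <- list(val = val, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= run$patience) break
    }
  }
  structure(list(params = best$params, config = config,
                 stats = ds_train$stats, run = run, history = history,
                 best_epoch = best$epoch),
            class = "sparsekin_checkpoint")
}

#' Save / load a checkpoint
#' @param ckpt checkpoint from [train_model()]
#' @param path file path (RDS)
#' @export
checkpoint_save <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "sparsekin_checkpoint")) stop("not a sparsekin checkpoint")
  ckpt
}

# batched window predictions for one feature matrix at the given end frames
.predict_ends <- function(ckpt, feats, ends, batch_size = 64L) {
  L <- ckpt$config$L
  preds <- matrix(0, length(ends), ckpt$config$d_out)
  for (start in seq(1, length(ends), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(ends))
    M0 <- matrix(0, length(idx) * L, ncol(feats))
    for (i in seq_along(idx)) {
      e <- ends[idx[i]]
      M0[((i - 1L) * L + 1L):(i * L), ] <- feats[(e - L + 1L):e, ]
    }
    preds[idx, ] <- model_forward(ckpt$params, list(M0 = M0, B = length(idx)),
                                  ckpt$config)$pred
  }
  preds
}

# reconstruct proximal orientations (swing composed with the sensed distal
# orientation) for a 40-wide table at the given frames
.reconstruct_proximal <- function(tbl, q_distal, frames) {
  out <- array(0, c(length(frames), 4, 4))
  for (j in 1:4) {
    qc <- (j - 1L) * 10L + 1:4
    sw <- quat_normalize(tbl[, qc, drop = FALSE])
    out[, j, ] <- quat_multiply(sw, q_distal[frames, j, , drop = TRUE])
  }
  out
}

#' Evaluate predictions for one capture
#'
#' Shared by checkpoint evaluation and ground-truth self-checks: given a
#' 40-wide prediction table aligned with `frames`, reconstructs proximal
#' orientations from the predicted swing and the sensed distal orientation,
#' maps them to endpoint positions, and computes the metric report against
#' the ground-truth swing mapped identically (so a perfect prediction
#' scores exactly zero error).
#'
#' @param pred N x 40 prediction table
#' @param truth the capture's ground-truth list
#' @param target N x 40 ground-truth target table aligned with `frames`
#' @param frames frame indices the rows correspond to
#' @return a `metrics_report`
#' @export
eval_capture <- function(pred, truth, target, frames) {
  qp_hat <- .reconstruct_proximal(pred, truth$q_distal, frames)
  qp_gt <- .reconstruct_proximal(target, truth$q_distal, frames)
  q_torso <- truth$q_torso[frames, , drop = FALSE]
  pos_hat <- proximal_positions(qp_hat, q_torso)
  pos_gt <- proximal_positions(qp_gt, q_torso)
  metrics_report(qp_hat, qp_gt, pos_hat, pos_gt)
}

#' Evaluate a checkpoint on held-out captures
#'
#' Predicts every frame from `L` onward (stride 1, causal windows), with or
#' without the post-processing stack, and aggregates frame-weighted metrics
#' over the captures.
#'
#' @param ckpt checkpoint
#' @param sims list of [simulate_imu_stream()] results (held-out)
#' @param postprocess apply joint-limit clamping + Kalman smoothing
#' @param noise_sigma optional additive channel noise (normalized units)
#'   injected into the features before inference
#' @param noise_seed seed for the noise draw
#' @param predictions optional precomputed [predict_captures()] output
#' @return list with `aggregate` (named metric means), `per_capture`
#'   (list of `metrics_report`), and `pred_omega` (mean denormalized
#'   predicted proximal angular speed, rad/s)
#' @export
evaluate_model <- function(ckpt, sims, postprocess = TRUE, noise_sigma = 0,
                           noise_seed = 1L, predictions = NULL) {
  if (is.null(predictions)) {
    predictions <- predict_captures(ckpt, sims, noise_sigma, noise_seed)
  }
  reports <- list()
  omega_means <- numeric(0)
  nfr <- numeric(0)
  for (pc in predictions) {
    pred <- if (postprocess) postprocess_predictions(pc$pred) else pc$pred
    reports[[length(reports) + 1L]] <-
      eval_capture(pred, pc$truth, pc$target, pc$frames)
    omega_means <- c(omega_means, .pred_omega_mean(pred, ckpt$stats))
    nfr <- c(nfr, length(pc$frames))
  }
  agg <- .aggregate_reports(reports, nfr)
  list(aggregate = agg, per_capture = reports,
       pred_omega = stats::weighted.mean(omega_means, nfr))
}

#' Raw per-capture window predictions
#'
#' Runs the causal sliding-window forward pass (stride 1, no
#' post-processing) over each capture and aligns the ground-truth targets;
#' the result can be fed to [evaluate_model()] repeatedly (e.g. with and
#' without post-processing) without recomputing the forward passes.
#'
#' @inheritParams evaluate_model
#' @return list per capture: `pred`, `frames`, `target`, `truth`
#' @export
predict_captures <- function(ckpt, sims, noise_sigma = 0, noise_seed = 1L) {
  L <- ckpt$config$L
  out <- list()
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    san <- sanitize_stream(calibrate_stream(s$stream))
    if (!san$accepted) stop("evaluation stream rejected: ", san$report)
    feats <- assemble_features(san$stream, ckpt$stats)
    if (noise_sigma > 0) {
      feats <- inject_noise(feats, noise_sigma, seed = noise_seed + i)
    }
    tt <- nrow(feats)
    if (tt < L) next
    frames <- L:tt
    pred <- .predict_ends(ckpt, feats, frames, ckpt$run$batch_size)
    target <- make_training_targets(s$truth, ckpt$stats)[frames, , drop = FALSE]
    out[[length(out) + 1L]] <- list(pred = pred, frames = frames,
                                    target = target, truth = s$truth)
  }
  out
}

# mean predicted proximal angular speed in physical units
.pred_omega_mean <- function(pred, stats) {
  sp <- matrix(0, nrow(pred), 4)
  for (j in 1:4) {
    vc <- (j - 1L) * 10L + 5:7
    w <- znorm_invert(pred[, vc, drop = FALSE], stats$tgt_mu_w[j],
                      stats$tgt_sigma_w[j])
    sp[, j] <- sqrt(rowSums(w * w))
  }
  mean(sp)
}

.aggregate_reports <- function(reports, nfr) {
  if (!length(reports)) stop("no captures long enough to evaluate")
  wmean <- function(f) stats::weighted.mean(vapply(reports, `[[`, numeric(1), f), nfr)
  list(mae_deg = wmean("mae_deg"), mpjpe_cm = wmean("mpjpe_cm"),
       pck5 = wmean("pck5"), pck10 = wmean("pck10"),
       pck_auc = wmean("pck_auc"), tse = wmean("tse"))
}

#' Causal frame-by-frame streaming inference
#'
#' Replays a raw stream through a FIFO window buffer: no output until 120
#' frames have been buffered, then one prediction per incoming frame using
#' only past frames.  Equivalent, frame for frame, to batch-mode
#' sliding-window inference on the same stream.
#'
#' During live operation a sensor can drop out for longer than the
#' sanitizer's interpolation window; rather than abort, the streaming path
#' holds the last valid pose of the affected channels (with a warning)
#' until data returns.
#'
#' @param ckpt checkpoint
#' @param stream raw `imu_stream`
#' @param postprocess apply the post-processing stack to the emitted series
#' @return list with `frames` (indices predictions correspond to) and
#'   `pred` (N x 40 matrix)
#' @export
infer_stream <- function(ckpt, stream, postprocess = TRUE) {
  L <- ckpt$config$L
  san <- sanitize_stream(calibrate_stream(.hold_last_pose(stream)))
  if (!san$accepted) stop("stream rejected: ", san$report)
  feats <- assemble_features(san$stream, ckpt$stats)
  tt <- nrow(feats)
  if (tt < L) {
    return(list(frames = integer(0), pred = matrix(0, 0, ckpt$config$d_out)))
  }
  preds <- matrix(0, tt - L + 1L, ckpt$config$d_out)
  buffer <- feats[1:(L - 1L), , drop = FALSE]          # FIFO warm-up
  for (t in L:tt) {
    buffer <- rbind(buffer, feats[t, , drop = FALSE])  # push
    if (nrow(buffer) > L) buffer <- buffer[-1L, , drop = FALSE]  # pop
    preds[t - L + 1L, ] <- model_forward(ckpt$params, buffer, ckpt$config)$pred
  }
  if (postprocess) preds <- postprocess_predictions(preds)
  list(frames = L:tt, pred = preds)
}

# forward-fill sensor dropout (non-finite runs) with the last valid frame;
# leading gaps are back-filled from the first valid frame
.hold_last_pose <- function(stream) {
  fill <- function(x) {
    bad <- !is.finite(x)
    if (!any(bad)) return(x)
    idx <- seq_along(x)
    good <- which(!bad)
    if (!length(good)) return(x)
    x[bad] <- x[good[pmax(1L, findInterval(idx[bad], good))]]
    x
  }
  held <- FALSE
  for (s in 1:5) {
    chans <- cbind(stream$q[, s, ], stream$w[, s, ], stream$a[, s, ])
    if (any(!is.finite(chans))) held <- TRUE
    for (c4 in 1:4) stream$q[, s, c4] <- fill(stream$q[, s, c4])
    for (c3 in 1:3) {
      stream$w[, s, c3] <- fill(stream$w[, s, c3])
      stream$a[, s, c3] <- fill(stream$a[, s, c3])
    }
  }
  if (held) warning("sensor dropout beyond the interpolation window: holding last pose")
  stream
}

#' Noise stress sweep
#'
#' Re-evaluates a checkpoint under increasing additive Gaussian channel
#' noise (normalized-feature units, inertial channels only) and tabulates
#' MPJPE, TSE and percentage MPJPE degradation relative to the clean run.
#'
#' @param ckpt checkpoint
#' @param sims held-out captures
#' @param sigmas numeric vector of noise levels (0 is prepended if absent)
#' @param seed base seed for the noise draws
#' @param postprocess apply post-processing during evaluation
#' @return data frame `sigma`, `mpjpe_cm`, `tse`, `degradation_pct`
#' @export
noise_sweep <- function(ckpt, sims, sigmas = c(0, 0.05, 0.1, 0.3, 0.5, 1),
                        seed = 1L, postprocess = TRUE) {
  sigmas <- sort(unique(c(0, sigmas)))
  rows <- lapply(seq_along(sigmas), function(i) {
    ev <- evaluate_model(ckpt, sims, postprocess = postprocess,
                         noise_sigma = sigmas[i], noise_seed = seed + 1000L * i)
    data.frame(sigma = sigmas[i], mpjpe_cm = ev$aggregate$mpjpe_cm,
               tse = ev$aggregate$tse)
  })
  out <- do.call(rbind, rows)
  out$degradation_pct <- 100 * (out$mpjpe_cm / out$mpjpe_cm[out$sigma == 0] - 1)
  out
}

#' Constant reference-pose baseline predictions
#'
#' Predicts the identity swing and zero (normalized mean) inertial state at
#' every frame — the "frozen T-pose" baseline any trained model must beat.
#'
#' @param n number of frames
#' @param stats `norm_stats` for the normalized-zero inertial blocks
#' @return N x 40 prediction matrix
#' @export
baseline_tpose <- function(n, stats) {
  row <- numeric(40)
  for (j in 1:4) {
    row[(j - 1L) * 10L + 1:4] <- quat_identity()
    row[(j - 1L) * 10L + 5:7] <- znorm_clamp(0, stats$tgt_mu_w[j], stats$tgt_sigma_w[j])
    row[(j - 1L) * 10L + 8:10] <- znorm_clamp(0, stats$tgt_mu_a[j], stats$tgt_sigma_a[j])
  }
  matrix(row, n, 40, byrow = TRUE)
}
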