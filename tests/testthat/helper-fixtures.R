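# shared fixtures built in code at test time

random_unit_quats <- function(n, seed = 1) {
  set.seed(seed)
  quat_normalize(matrix(rnorm(n * 4), n, 4))
}

# static stream: identity orientations, zero inertial channels
static_stream <- function(n = 150) {
  q <- array(0, c(n, 5, 4))
  q[, , 1] <- 1
  imu_stream(seq(0, by = 1 / 60, length.out = n), q,
             array(0, c(n, 5, 3)), array(0, c(n, 5, 3)))
}

# neutral stats (mu 0, sigma 1 everywhere) for layout-level tests
unit_stats <- function() {
  structure(list(mu_w = rep(0, 5), sigma_w = rep(1, 5),
                 mu_a = rep(0, 5), sigma_a = rep(1, 5),
                 tgt_mu_w = rep(0, 4), tgt_sigma_w = rep(1, 4),
                 tgt_mu_a = rep(0, 4), tgt_sigma_a = rep(1, 4)),
            class = "norm_stats")
}

# small ADL capture reused across pipeline tests (memoised per session)
.fixture_env <- new.env(parent = emptyenv())

small_adl_sim <- function(seed = 21, duration = 20) {
  key <- paste0("adl_", seed, "_", duration)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_imu_stream(
      generate_adl_motion(duration = duration, seed = seed),
      sim_config(seed = seed + 1000L, duration = 2))
  }
  .fixture_env[[key]]
}

# tiny trained checkpoint shared by pipeline tests: 2 short captures,
# reduced width, 2 epochs — enough for structural/behavioural checks
tiny_checkpoint <- function() {
  if (is.null(.fixture_env$ckpt)) {
    sims <- list(small_adl_sim(21), small_adl_sim(22))
    val <- list(small_adl_sim(23, duration = 10))
    ds <- build_dataset(sims, L = 120L, stride = 30L)
    dsv <- build_dataset(val, stats = ds$stats, L = 120L, stride = 30L)
    cfg <- model_config(d_model = 32L, n_layers = 1L, n_heads = 4L,
                        d_ff = 64L, dropout = 0)
    run <- run_config(lr = 1e-3, epochs = 2L, batch_size = 16L, seed = 42L,
                      r = 0)
    .fixture_env$ckpt <- train_model(ds, dsv, cfg, run)
  }
  .fixture_env$ckpt
}
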