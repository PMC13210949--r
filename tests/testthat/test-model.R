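test_that("positional encoding matches the sinusoidal closed form", {
  pe <- positional_encoding(120, 64)
  expect_equal(pe[1, seq(1, 63, by = 2)], rep(0, 32))   # sin(0)
  expect_equal(pe[1, seq(2, 64, by = 2)], rep(1, 32))   # cos(0)
  pos <- 17
  expect_equal(pe[pos + 1, 1], sin(pos))                # column 0 frequency 1
  # independent direct-formula evaluation of the full table
  oracle <- matrix(0, 120, 64)
  for (p in 0:119) for (i in 0:31) {
    oracle[p + 1, 2 * i + 1] <- sin(p / 10000^(2 * i / 64))
    oracle[p + 1, 2 * i + 2] <- cos(p / 10000^(2 * i / 64))
  }
  expect_equal(pe, oracle, tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
})

test_that("scaled dot-product attention is row-stochastic and matches a loop oracle", {
  set.seed(4)
  # single key/value: output equals that value for any query
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rnorm(4), 1, 4)
  V <- matrix(rnorm(4), 1, 4)
  att <- attention(Q, K, V)
  expect_equal(att$out, V[rep(1, 3), , drop = FALSE])
  # rows sum to one
  Q <- matrix(rnorm(16), 4, 4); K <- matrix(rnorm(16), 4, 4)
  V <- matrix(rnorm(16), 4, 4)
  att <- attention(Q, K, V)
  expect_equal(rowSums(att$weights), rep(1, 4), tolerance = 1e-6)
  # element-wise brute-force softmax oracle on the 4x4 case
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) {
    s <- numeric(4)
    for (j in 1:4) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
    w <- exp(s) / sum(exp(s))
    for (c in 1:4) oracle[i, c] <- sum(w * V[, c])
  }
  expect_equal(att$out, oracle, tolerance = 1e-12)
})

test_that("encoder forward is deterministic in eval mode and shape-checked", {
  cfg <- model_config(d_model = 16L, n_layers = 2L, n_heads = 2L, d_ff = 32L,
                      L = 10L, dropout = 0.1)
  p <- model_init(cfg, seed = 1)
  X <- array(rnorm(3 * 10 * 50), c(3, 10, 50))
  f1 <- model_forward(p, X, cfg)
  f2 <- model_forward(p, X, cfg)
  expect_identical(f1$pred, f2$pred)
  expect_equal(dim(f1$pred), c(3, 40))
  bad <- array(rnorm(3 * 9 * 50), c(3, 9, 50))
  expect_error(model_forward(p, bad, cfg))
})

test_that("zeroed attention and feed-forward outputs leave the residual stream at embedding + PE", {
  cfg <- model_config(d_model = 16L, n_layers = 2L, n_heads = 2L, d_ff = 32L,
                      L = 10L, dropout = 0)
  p <- model_init(cfg, seed = 2)
  for (l in 1:2) {
    p[[paste0("Wo", l)]][] <- 0; p[[paste0("bo", l)]][] <- 0
    p[[paste0("W2", l)]][] <- 0; p[[paste0("b2", l)]][] <- 0
  }
  X <- array(rnorm(2 * 10 * 50), c(2, 10, 50))
  fw <- model_forward(p, X, cfg, training = TRUE)
  M0 <- matrix(aperm(X, c(2, 1, 3)), 20, 50)
  embedded <- M0 %*% p$We + positional_encoding(10, 16)[rep(1:10, 2), ]
  expect_equal(fw$cache$H_final, embedded, tolerance = 1e-12)
})

test_that("multitask head reads only the final frame and normalizes swing blocks", {
  cfg <- model_config(d_model = 16L, n_layers = 1L, n_heads = 2L, d_ff = 32L,
                      L = 10L, dropout = 0)
  p <- model_init(cfg, seed = 3)
  X <- array(rnorm(2 * 10 * 50), c(2, 10, 50))
  fw <- model_forward(p, X, cfg, training = TRUE)
  expect_equal(ncol(fw$pred), 40)
  for (j in 1:4) {
    expect_equal(sqrt(rowSums(fw$pred[, (j - 1) * 10 + 1:4]^2)), rep(1, 2),
                 tolerance = 1e-6)
  }
  # the head input is exactly the normalized latent of the last frame
  expect_equal(fw$cache$zL, fw$cache$lnF$y[c(10, 20), , drop = FALSE])
})

test_that("the receptive field spans the whole window (earliest frame matters)", {
  cfg <- model_config(d_model = 16L, n_layers = 2L, n_heads = 2L, d_ff = 32L,
                      L = 12L, dropout = 0)
  p <- model_init(cfg, seed = 4)
  X <- array(rnorm(1 * 12 * 50), c(1, 12, 50))
  base <- model_forward(p, X, cfg)$pred
  X2 <- X
  X2[1, 1, ] <- X2[1, 1, ] + 0.5      # perturb frame t - L + 1
  expect_gt(max(abs(model_forward(p, X2, cfg)$pred - base)), 1e-6)
})

test_that("analytic gradients agree with finite differences across all parameter kinds", {
  cfg <- model_config(d_model = 8L, n_layers = 1L, n_heads = 2L, d_ff = 16L,
                      L = 6L, dropout = 0)
  p <- model_init(cfg, seed = 3)
  set.seed(91)
  X <- array(rnorm(2 * 6 * 50), c(2, 6, 50))
  Y <- matrix(rnorm(2 * 40), 2, 40)
  for (j in 1:4) Y[, (j - 1) * 10 + 1:4] <- quat_normalize(Y[, (j - 1) * 10 + 1:4])
  lossfn <- function(pp) {
    fw <- model_forward(pp, X, cfg, training = TRUE)
    total_loss(fw$pred, Y, grad = TRUE)
  }
  l <- lossfn(p)
  fw <- model_forward(p, X, cfg, training = TRUE)
  g <- model_backward(p, fw$cache, l$grad, cfg)
  eps <- 1e-6
  for (nm in c("We", "be", "Wq1", "Wk1", "Wv1", "Wo1", "ln1_g1", "ln2_b1",
               "W11", "b11", "W21", "lnF_g", "Wh1", "bh4")) {
    idx <- sample(length(p[[nm]]), min(4, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossfn(pp)$total - lossfn(pm)$total) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("full-scale configuration parameter count is within 2% of 4.74M", {
  p <- model_init(model_config(), seed = 1)
  n <- model_param_count(p)
  expect_lt(abs(n - 4743946) / 4743946, 0.02)
})

test_that("the model can drive the loss below 1e-3 on one repeated batch", {
  cfg <- model_config(d_model = 32L, n_layers = 2L, n_heads = 4L, d_ff = 64L,
                      L = 30L, dropout = 0)
  p <- model_init(cfg, seed = 5)
  set.seed(77)
  B <- 8L
  M0 <- matrix(rnorm(B * 30 * 50), B * 30, 50)
  Y <- matrix(rnorm(B * 40) * 0.3, B, 40)
  for (j in 1:4) Y[, (j - 1) * 10 + 1:4] <- quat_normalize(matrix(rnorm(B * 4), B, 4))
  opt <- sparsekin:::.adamw_init(p)
  final <- Inf
  for (i in 1:500) {
    fw <- model_forward(p, list(M0 = M0, B = B), cfg, training = TRUE)
    l <- total_loss(fw$pred, Y, grad = TRUE)
    final <- l$total
    if (final < 1e-3) break
    g <- model_backward(p, fw$cache, l$grad, cfg)
    u <- sparsekin:::.adamw_update(opt, p, g, 3e-3, 0)
    opt <- u$opt; p <- u$params
  }
  expect_lt(final, 1e-3)
})
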