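#' Encoder-only self-attention sequence-to-vector regressor
#'
#' Maps an L x 50 feature window to the 40-dim kinematic state of the four
#' uninstrumented proximal joints.  The topology is a linear input embedding
#' (50 -> d_model), additive sinusoidal positional encoding, a stack of
#' pre-layer-norm encoder blocks (multi-head self-attention + residual, then
#' a GELU feed-forward expansion + residual), a final layer norm, and four
#' parallel per-joint linear heads of width 10 reading the latent state of
#' the window's last frame only.  Predicted swing quaternion blocks are
#' L2-normalized before the loss and before output.
#'
#' Forward and backward passes are implemented directly in matrix code; the
#' backward pass returns exact analytic gradients (verified against finite
#' differences in the test suite), so the model can be trained with the
#' package's AdamW optimizer without an external autodiff framework.
#'
#' @name model
NULL

#' Model configuration
#'
#' Defaults mirror the full-scale architecture: 6 layers, d_model 256,
#' 8 heads, feed-forward width 1024, dropout 0.1, window L = 120, input
#' width 50, output width 40.  Desk-scale studies use the documented
#' reduction (d_model 64, 2 layers, 4 heads, d_ff 256).
#'
#' @param d_model latent width (divisible by `n_heads`)
#' @param n_layers encoder depth
#' @param n_heads attention heads
#' @param d_ff feed-forward expansion width
#' @param dropout dropout probability (training mode only)
#' @param L window length in frames
#' @param d_in per-frame input width
#' @param d_out output width (4 joints x 10)
#' @return a `model_config` list
#' @export
model_config <- function(d_model = 256L, n_layers = 6L, n_heads = 8L,
                         d_ff = 1024L, dropout = 0.1, L = 120L,
                         d_in = 50L, d_out = 40L) {
  stopifnot(d_model %% n_heads == 0L, d_model > 0L, n_layers > 0L,
            n_heads > 0L, d_ff > 0L, L > 0L, d_in > 0L, d_out > 0L,
            dropout >= 0, dropout < 1)
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, L = as.integer(L), d_in = as.integer(d_in),
                 d_out = as.integer(d_out)), class = "model_config")
}

#' Reduced configuration for CPU desk-scale studies
#' @param L window length in frames
#' @return a `model_config` with d_model 64, 2 layers, 4 heads, d_ff 256
#' @export
model_config_small <- function(L = 120L) {
  model_config(d_model = 64L, n_layers = 2L, n_heads = 4L, d_ff = 256L, L = L)
}

#' Sinusoidal positional encoding table
#'
#' `PE[pos, 2i+1] = sin(pos / 10000^(2i/d_model))` and
#' `PE[pos, 2i+2] = cos(...)` (columns 1-based), for positions
#' `0 .. L-1`.  Added to the input embedding to give the otherwise
#' permutation-invariant attention stack a notion of temporal order.
#'
#' @param L number of positions
#' @param d_model embedding width
#' @return L x d_model matrix with values in `[-1, 1]`
#' @export
positional_encoding <- function(L, d_model) {
  pos <- 0:(L - 1)
  pe <- matrix(0, L, d_model)
  i <- 0:(ceiling(d_model / 2) - 1)
  freq <- 1 / 10000^(2 * i / d_model)
  ang <- outer(pos, freq)
  pe[, 2 * i + 1] <- sin(ang)
  odd <- 2 * i + 2
  keep <- odd <= d_model
  pe[, odd[keep]] <- cos(ang[, keep, drop = FALSE])
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with row-wise softmax; `d_k` is taken from
#' `ncol(Q)` unless given.
#'
#' @param Q,K,V conformable matrices (rows = positions)
#' @param d_k key dimensionality used in the scaling
#' @return list with the output matrix `out` and the attention `weights`
#' @export
attention <- function(Q, K, V, d_k = ncol(Q)) {
  S <- Q %*% t(K) / sqrt(d_k)
  A <- .softmax_rows(S)
  list(out = A %*% V, weights = A)
}

.softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# tanh-form GELU (the standard fast approximation of x * Phi(x));
# powers written as products — noticeably faster than `^` on large matrices.
# The forward returns the tanh term so the backward can reuse it.
.gelu_c <- sqrt(2 / pi)
.gelu_fwd <- function(x) {
  x2 <- x * x
  th <- tanh(.gelu_c * (x + 0.044715 * x * x2))
  list(y = 0.5 * x * (1 + th), th = th, x2 = x2)
}
.gelu <- function(x) .gelu_fwd(x)$y
.gelu_grad_cached <- function(x, th, x2) {
  0.5 * (1 + th) + 0.5 * x * (1 - th * th) * .gelu_c * (1 + 0.134145 * x2)
}
.gelu_grad <- function(x) {
  f <- .gelu_fwd(x)
  .gelu_grad_cached(x, f$th, f$x2)
}

# row-wise layer norm; returns normalized y, plus cache for backward
.layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  list(y = sweep(Xhat * 1, 2, gamma, `*`) + rep(beta, each = nrow(X)),
       Xhat = Xhat, inv = inv)
}

.layernorm_bwd <- function(dY, cache, gamma) {
  Xhat <- cache$Xhat
  dXhat <- sweep(dY, 2, gamma, `*`)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- (dXhat - m1 - Xhat * m2) * cache$inv
  list(dX = dX, dgamma = colSums(dY * Xhat), dbeta = colSums(dY))
}

.glorot <- function(rng, n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng$runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model weights
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains; the draw is
#' fully determined by `seed` and never touches the global RNG stream.
#'
#' @param config a [model_config()]
#' @param seed integer seed for the weight draw
#' @return named list of parameter matrices/vectors
#' @export
model_init <- function(config, seed = 42L) {
  rng <- .seeded_rng(seed)
  d <- config$d_model
  p <- list(
    We = .glorot(rng, config$d_in, d), be = numeric(d),
    lnF_g = rep(1, d), lnF_b = numeric(d)
  )
  for (l in seq_len(config$n_layers)) {
    p[[paste0("Wq", l)]] <- .glorot(rng, d, d)
    p[[paste0("Wk", l)]] <- .glorot(rng, d, d)
    p[[paste0("Wv", l)]] <- .glorot(rng, d, d)
    p[[paste0("Wo", l)]] <- .glorot(rng, d, d)
    p[[paste0("bq", l)]] <- numeric(d)
    p[[paste0("bk", l)]] <- numeric(d)
    p[[paste0("bv", l)]] <- numeric(d)
    p[[paste0("bo", l)]] <- numeric(d)
    p[[paste0("ln1_g", l)]] <- rep(1, d)
    p[[paste0("ln1_b", l)]] <- numeric(d)
    p[[paste0("ln2_g", l)]] <- rep(1, d)
    p[[paste0("ln2_b", l)]] <- numeric(d)
    p[[paste0("W1", l)]] <- .glorot(rng, d, config$d_ff)
    p[[paste0("b1", l)]] <- numeric(config$d_ff)
    p[[paste0("W2", l)]] <- .glorot(rng, config$d_ff, d)
    p[[paste0("b2", l)]] <- numeric(d)
  }
  for (j in 1:4) {
    p[[paste0("Wh", j)]] <- .glorot(rng, d, 10L)
    p[[paste0("bh", j)]] <- numeric(10L)
  }
  p
}

#' Count trainable parameters
#' @param params list from [model_init()]
#' @return integer total
#' @export
model_param_count <- function(params) {
  sum(vapply(params, length, integer(1)))
}

#' Forward pass
#'
#' @param params weights from [model_init()]
#' @param X input array `B x L x d_in` (a single `L x d_in` matrix is
#'   treated as batch size 1)
#' @param config the [model_config()]
#' @param training logical; enables dropout and gradient caching
#' @param rng internal RNG (from training loop) for dropout masks
#' @return list with `pred` (B x d_out, swing blocks unit-normalized),
#'   `raw` (pre-normalization head output) and, when `training`, a `cache`
#'   for [model_backward()]
#' @export
model_forward <- function(params, X, config, training = FALSE, rng = NULL) {
  if (is.list(X) && !is.null(X$M0)) {
    # pre-flattened input: rows ordered frame-within-window, one window block
    # after another (what the batch gatherer produces)
    M0 <- X$M0; B <- X$B; L <- config$L
    stopifnot(nrow(M0) == B * L, ncol(M0) == config$d_in)
  } else {
    if (is.matrix(X)) X <- array(X, c(1L, nrow(X), ncol(X)))
    B <- dim(X)[1]; L <- dim(X)[2]
    stopifnot(L == config$L, dim(X)[3] == config$d_in)
    # rows ordered t within b: aperm gives (t, b, din) -> flatten t fastest per b
    M0 <- matrix(aperm(X, c(2, 1, 3)), B * L, config$d_in)
  }
  d <- config$d_model; h <- config$n_heads; dk <- d %/% h
  keep <- if (training && config$dropout > 0) 1 - config$dropout else 1

  H <- M0 %*% params$We + rep(params$be, each = B * L)
  pe <- positional_encoding(L, d)
  H <- H + pe[rep(seq_len(L), times = B), ]
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)

  cache <- if (training) list(M0 = M0, B = B, L = L) else NULL
  layer_caches <- vector("list", config$n_layers)

  for (l in seq_len(config$n_layers)) {
    lc <- list(H_in = H)
    ln1 <- .layernorm_fwd(H, params[[paste0("ln1_g", l)]], params[[paste0("ln1_b", l)]])
    lc$ln1 <- ln1
    Q <- ln1$y %*% params[[paste0("Wq", l)]] + rep(params[[paste0("bq", l)]], each = B * L)
    K <- ln1$y %*% params[[paste0("Wk", l)]] + rep(params[[paste0("bk", l)]], each = B * L)
    V <- ln1$y %*% params[[paste0("Wv", l)]] + rep(params[[paste0("bv", l)]], each = B * L)
    lc$Q <- Q; lc$K <- K; lc$V <- V
    O <- matrix(0, B * L, d)
    Aws <- if (training) vector("list", B * h) else NULL
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (k in seq_len(h)) {
        ck <- ((k - 1L) * dk + 1L):(k * dk)
        S <- tcrossprod(Q[rb, ck, drop = FALSE], K[rb, ck, drop = FALSE]) / sqrt(dk)
        A <- .softmax_rows(S)
        if (training) Aws[[(b - 1L) * h + k]] <- A
        O[rb, ck] <- A %*% V[rb, ck, drop = FALSE]
      }
    }
    lc$A <- Aws; lc$O <- O
    attn <- O %*% params[[paste0("Wo", l)]] + rep(params[[paste0("bo", l)]], each = B * L)
    if (keep < 1) {
      mask1 <- matrix(rng$runif(length(attn)) < keep, nrow(attn)) / keep
      attn <- attn * mask1
      lc$mask1 <- mask1
    }
    H <- H + attn
    ln2 <- .layernorm_fwd(H, params[[paste0("ln2_g", l)]], params[[paste0("ln2_b", l)]])
    lc$H_mid <- H; lc$ln2 <- ln2
    Z1 <- ln2$y %*% params[[paste0("W1", l)]] + rep(params[[paste0("b1", l)]], each = B * L)
    gl <- .gelu_fwd(Z1)
    G <- gl$y
    ff <- G %*% params[[paste0("W2", l)]] + rep(params[[paste0("b2", l)]], each = B * L)
    if (keep < 1) {
      mask2 <- matrix(rng$runif(length(ff)) < keep, nrow(ff)) / keep
      ff <- ff * mask2
      lc$mask2 <- mask2
    }
    if (training) { lc$Z1 <- Z1; lc$G <- G; lc$th <- gl$th; lc$x2 <- gl$x2 }
    H <- H + ff
    layer_caches[[l]] <- lc
  }

  lnF <- .layernorm_fwd(H, params$lnF_g, params$lnF_b)
  zL <- lnF$y[seq_len(B) * L, , drop = FALSE]           # last frame per sample
  raw <- matrix(0, B, config$d_out)
  for (j in 1:4) {
    raw[, (j - 1L) * 10L + 1:10] <- zL %*% params[[paste0("Wh", j)]] +
      rep(params[[paste0("bh", j)]], each = B)
  }
  pred <- raw
  qnorms <- matrix(0, B, 4)
  for (j in 1:4) {
    qc <- (j - 1L) * 10L + 1:4
    n <- sqrt(rowSums(raw[, qc, drop = FALSE]^2))
    n <- pmax(n, 1e-12)
    qnorms[, j] <- n
    pred[, qc] <- raw[, qc, drop = FALSE] / n
  }

  if (training) {
    cache$layers <- layer_caches
    cache$lnF <- lnF
    cache$H_final <- H
    cache$zL <- zL
    cache$raw <- raw
    cache$pred <- pred
    cache$qnorms <- qnorms
  }
  list(pred = pred, raw = raw, cache = cache)
}

#' Backward pass
#'
#' Given the gradient of a scalar loss with respect to the normalized
#' prediction matrix, returns gradients for every parameter (same structure
#' as the parameter list) and propagates exactly through the quaternion
#' normalization, the per-joint heads, the final layer norm, and each
#' encoder block in reverse.
#'
#' @param params model weights
#' @param cache forward cache from `model_forward(..., training = TRUE)`
#' @param d_pred gradient B x d_out with respect to `pred`
#' @param config the [model_config()]
#' @return named list of gradients
#' @export
model_backward <- function(params, cache, d_pred, config) {
  B <- cache$B; L <- cache$L
  d <- config$d_model; h <- config$n_heads; dk <- d %/% h
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  grads <- list()

  # quaternion-normalization backward: y = r / ||r||
  d_raw <- d_pred
  for (j in 1:4) {
    qc <- (j - 1L) * 10L + 1:4
    qn <- cache$pred[, qc, drop = FALSE]
    g <- d_pred[, qc, drop = FALSE]
    d_raw[, qc] <- (g - qn * rowSums(g * qn)) / cache$qnorms[, j]
  }

  d_zL <- matrix(0, B, d)
  for (j in 1:4) {
    cols <- (j - 1L) * 10L + 1:10
    gj <- d_raw[, cols, drop = FALSE]
    grads[[paste0("Wh", j)]] <- crossprod(cache$zL, gj)
    grads[[paste0("bh", j)]] <- colSums(gj)
    d_zL <- d_zL + gj %*% t(params[[paste0("Wh", j)]])
  }

  dYF <- matrix(0, B * L, d)
  dYF[seq_len(B) * L, ] <- d_zL
  lnb <- .layernorm_bwd(dYF, cache$lnF, params$lnF_g)
  grads$lnF_g <- lnb$dgamma; grads$lnF_b <- lnb$dbeta
  dH <- lnb$dX

  for (l in rev(seq_len(config$n_layers))) {
    lc <- cache$layers[[l]]
    # FFN sublayer
    dff <- dH
    if (!is.null(lc$mask2)) dff <- dff * lc$mask2
    grads[[paste0("W2", l)]] <- crossprod(lc$G, dff)
    grads[[paste0("b2", l)]] <- colSums(dff)
    dG <- dff %*% t(params[[paste0("W2", l)]])
    dZ1 <- dG * .gelu_grad_cached(lc$Z1, lc$th, lc$x2)
    grads[[paste0("W1", l)]] <- crossprod(lc$ln2$y, dZ1)
    grads[[paste0("b1", l)]] <- colSums(dZ1)
    dln2y <- dZ1 %*% t(params[[paste0("W1", l)]])
    lnb2 <- .layernorm_bwd(dln2y, lc$ln2, params[[paste0("ln2_g", l)]])
    grads[[paste0("ln2_g", l)]] <- lnb2$dgamma
    grads[[paste0("ln2_b", l)]] <- lnb2$dbeta
    dH <- dH + lnb2$dX                                   # residual join

    # attention sublayer
    dattn <- dH
    if (!is.null(lc$mask1)) dattn <- dattn * lc$mask1
    grads[[paste0("Wo", l)]] <- crossprod(lc$O, dattn)
    grads[[paste0("bo", l)]] <- colSums(dattn)
    dO <- dattn %*% t(params[[paste0("Wo", l)]])
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (k in seq_len(h)) {
        ck <- ((k - 1L) * dk + 1L):(k * dk)
        A <- lc$A[[(b - 1L) * h + k]]
        dOb <- dO[rb, ck, drop = FALSE]
        Vb <- lc$V[rb, ck, drop = FALSE]
        dA <- tcrossprod(dOb, Vb)
        dV[rb, ck] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rb, ck] <- dS %*% lc$K[rb, ck, drop = FALSE] / sqrt(dk)
        dK[rb, ck] <- crossprod(dS, lc$Q[rb, ck, drop = FALSE]) / sqrt(dk)
      }
    }
    grads[[paste0("Wq", l)]] <- crossprod(lc$ln1$y, dQ)
    grads[[paste0("bq", l)]] <- colSums(dQ)
    grads[[paste0("Wk", l)]] <- crossprod(lc$ln1$y, dK)
    grads[[paste0("bk", l)]] <- colSums(dK)
    grads[[paste0("Wv", l)]] <- crossprod(lc$ln1$y, dV)
    grads[[paste0("bv", l)]] <- colSums(dV)
    dln1y <- dQ %*% t(params[[paste0("Wq", l)]]) +
      dK %*% t(params[[paste0("Wk", l)]]) +
      dV %*% t(params[[paste0("Wv", l)]])
    lnb1 <- .layernorm_bwd(dln1y, lc$ln1, params[[paste0("ln1_g", l)]])
    grads[[paste0("ln1_g", l)]] <- lnb1$dgamma
    grads[[paste0("ln1_b", l)]] <- lnb1$dbeta
    dH <- dH + lnb1$dX
  }

  grads$We <- crossprod(cache$M0, dH)
  grads$be <- colSums(dH)
  grads
}
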