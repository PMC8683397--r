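# Internal 1-D convolutional network primitives.
#
# The transformation-recognition trunk is three blocks of two same-padded
# 1-D convolutions (leaky ReLU) followed by max pooling, then global max
# pooling. No deep-learning runtime is assumed: forward and backward passes
# are written against BLAS matrix products, with convolutions evaluated as
# a sum over kernel taps (one tall-skinny matrix product per tap), which is
# both exact and fast at the channel widths used here.
#
# Batch tensors are R arrays with dim (n, L, C): sample index fastest, so a
# (n, L, C) slice flattens column-major to an (n*L) x C matrix for free.

conv1d_forward <- function(X, W, b) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; Cout <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(n, L + 2L * pad, Cin))
  Xp[, pad + seq_len(L), ] <- X
  Ymat <- matrix(rep(b, each = n * L), n * L, Cout)
  for (j in seq_len(k)) {
    Xj <- matrix(Xp[, j:(j + L - 1L), , drop = FALSE], n * L, Cin)
    Ymat <- Ymat + Xj %*% matrix(W[j, , ], Cin, Cout)
  }
  array(Ymat, c(n, L, Cout))
}

conv1d_backward <- function(X, W, dY) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; Cout <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(n, L + 2L * pad, Cin))
  Xp[, pad + seq_len(L), ] <- X
  dYmat <- matrix(dY, n * L, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, c(n, L + 2L * pad, Cin))
  for (j in seq_len(k)) {
    rng <- j:(j + L - 1L)
    Xj <- matrix(Xp[, rng, , drop = FALSE], n * L, Cin)
    dW[j, , ] <- crossprod(Xj, dYmat)
    dXj <- dYmat %*% t(matrix(W[j, , ], Cin, Cout))
    dXp[, rng, ] <- dXp[, rng, , drop = FALSE] + array(dXj, c(n, L, Cin))
  }
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE],
       dW = dW, db = colSums(dYmat))
}

leaky_forward <- function(X, slope) {
  neg <- X < 0
  X[neg] <- X[neg] * slope
  list(Y = X, neg = neg)
}

leaky_backward <- function(dY, neg, slope) {
  dY[neg] <- dY[neg] * slope
  dY
}

maxpool_forward <- function(X, p) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; C <- d[3L]
  stopifnot(L %% p == 0L)
  Lo <- L %/% p
  Xr <- array(X, c(n, p, Lo, C))
  Y <- array(Xr[, 1L, , , drop = FALSE], c(n, Lo, C))
  A <- array(1L, c(n, Lo, C))
  for (j in 2:p) {
    Xj <- array(Xr[, j, , , drop = FALSE], c(n, Lo, C))
    m <- Xj > Y
    Y[m] <- Xj[m]
    A[m] <- j
  }
  list(Y = Y, argmax = A, L = L)
}

maxpool_backward <- function(dY, pool_cache, p) {
  d <- dim(dY); n <- d[1L]; Lo <- d[2L]; C <- d[3L]
  dXr <- array(0, c(n, p, Lo, C))
  A <- pool_cache$argmax
  # linear index into (n, p, Lo, C) at (i, A, lo, c)
  i <- rep(seq_len(n), times = Lo * C)
  lo <- rep(rep(seq_len(Lo), each = n), times = C)
  cc <- rep(seq_len(C), each = n * Lo)
  lin <- i + (as.vector(A) - 1L) * n + (lo - 1L) * (n * p) + (cc - 1L) * (n * p * Lo)
  dXr[lin] <- as.vector(dY)
  array(dXr, c(n, pool_cache$L, C))
}

global_maxpool_forward <- function(X) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; C <- d[3L]
  Y <- matrix(X[, 1L, ], n, C)
  A <- matrix(1L, n, C)
  if (L > 1L) {
    for (j in 2:L) {
      Xj <- matrix(X[, j, ], n, C)
      m <- Xj > Y
      Y[m] <- Xj[m]
      A[m] <- j
    }
  }
  list(Y = Y, argmax = A, L = L)
}

global_maxpool_backward <- function(dY, cache, n, C) {
  dX <- array(0, c(n, cache$L, C))
  i <- rep(seq_len(n), times = C)
  cc <- rep(seq_len(C), each = n)
  lin <- i + (as.vector(cache$argmax) - 1L) * n + (cc - 1L) * (n * cache$L)
  dX[lin] <- as.vector(dY)
  dX
}

# ---- trunk ----------------------------------------------------------------

init_trunk <- function(cfg) {
  widths <- cfg$widths; kernels <- cfg$kernels
  cins <- c(1L, widths[1L], widths[1L], widths[2L], widths[2L], widths[3L])
  couts <- c(widths[1L], widths[1L], widths[2L], widths[2L], widths[3L], widths[3L])
  ks <- rep(kernels, each = 2L)
  gain <- if (is.null(cfg$init_gain)) 1 else cfg$init_gain
  params <- list()
  for (l in seq_len(6L)) {
    fan_in <- ks[l] * cins[l]
    params[[paste0("conv", l, ".W")]] <-
      array(stats::rnorm(ks[l] * cins[l] * couts[l], 0, gain * sqrt(2 / fan_in)),
            c(ks[l], cins[l], couts[l]))
    params[[paste0("conv", l, ".b")]] <- numeric(couts[l])
  }
  params
}

trunk_forward <- function(params, Xmat, cfg, keep_cache = FALSE) {
  n <- nrow(Xmat)
  X <- array(Xmat, c(n, ncol(Xmat), 1L))
  cache <- if (keep_cache) list() else NULL
  l <- 0L
  for (b in seq_len(3L)) {
    for (cpb in seq_len(2L)) {
      l <- l + 1L
      W <- params[[paste0("conv", l, ".W")]]
      bb <- params[[paste0("conv", l, ".b")]]
      if (keep_cache) cache[[paste0("in", l)]] <- X
      Z <- conv1d_forward(X, W, bb)
      act <- leaky_forward(Z, cfg$leaky)
      if (keep_cache) cache[[paste0("neg", l)]] <- act$neg
      X <- act$Y
    }
    pf <- maxpool_forward(X, cfg$pool)
    if (keep_cache) cache[[paste0("pool", b)]] <- pf
    X <- pf$Y
  }
  gmp <- global_maxpool_forward(X)
  if (keep_cache) {
    cache$gmp <- gmp
    cache$final_dim <- dim(X)
  }
  list(features = gmp$Y, cache = cache)
}

trunk_backward <- function(params, cfg, cache, dF) {
  n <- nrow(dF); C3 <- ncol(dF)
  dX <- global_maxpool_backward(dF, cache$gmp, n, C3)
  grads <- list()
  l <- 6L
  for (b in 3:1) {
    dX <- maxpool_backward(dX, cache[[paste0("pool", b)]], cfg$pool)
    for (cpb in 1:2) {
      dX <- leaky_backward(dX, cache[[paste0("neg", l)]], cfg$leaky)
      bw <- conv1d_backward(cache[[paste0("in", l)]],
                            params[[paste0("conv", l, ".W")]], dX)
      grads[[paste0("conv", l, ".W")]] <- bw$dW
      grads[[paste0("conv", l, ".b")]] <- bw$db
      dX <- bw$dX
      l <- l - 1L
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- losses ----------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy with optional positive-class weight; returns the mean
# loss and the gradient w.r.t. logits (already divided by element count).
bce_loss <- function(Z, Y, pos_weight = 1) {
  P <- sigmoid(Z)
  eps <- 1e-12
  loss <- -sum(pos_weight * Y * log(P + eps) + (1 - Y) * log(1 - P + eps)) / length(Z)
  dZ <- ((1 - Y) * P - pos_weight * Y * (1 - P)) / length(Z)
  list(loss = loss, dZ = dZ)
}

softmax_probs <- function(Z) {
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

# Multiclass cross-entropy over softmax logits; Y is a one-hot row matrix.
# Returns the mean loss and the gradient w.r.t. logits (divided by row count).
softmax_ce_loss <- function(Z, Y) {
  P <- softmax_probs(Z)
  n <- nrow(Z)
  loss <- -sum(Y * log(P + 1e-12)) / n
  list(loss = loss, dZ = (P - Y) / n, P = P)
}

mae_loss <- function(pred, y) {
  r <- pred - y
  list(loss = mean(abs(r)), dpred = sign(r) / length(r))
}
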