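# Low-level layer primitives. Activations live in (N, T, F) arrays
# (batch, timestep, feature); dense/batch-norm operate on (M, F) matrices.
# Every *_fw returns what its *_bw needs in `cache`; backward passes return
# parameter gradients plus the gradient w.r.t. the layer input.

as_mat <- function(x) {            # (N, T, F) -> (N*T, F) view
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_arr <- function(x, N, T) {      # (N*T, F) -> (N, T, F)
  dim(x) <- c(N, T, ncol(x))
  x
}

# 1-D convolution, stride 1, "same" zero padding, odd kernel, im2col form:
# the k shifted views of the zero-padded input are laid side by side so the
# whole convolution is a single matrix product.
# x: (N, T, Fin); W: (k, Fin, Fout); b: length Fout.
conv1d_fw <- function(x, W, b) {
  d <- dim(x); N <- d[1]; T <- d[2]; Fin <- d[3]
  k <- dim(W)[1]; Fout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(N, T + 2L * pad, Fin))
  xp[, (pad + 1L):(pad + T), ] <- x
  X2 <- matrix(0, N * T, k * Fin)
  for (j in seq_len(k)) {
    xs <- xp[, j:(j + T - 1L), , drop = FALSE]
    dim(xs) <- c(N * T, Fin)
    X2[, ((j - 1L) * Fin + 1L):(j * Fin)] <- xs
  }
  Wm <- matrix(aperm(W, c(2L, 1L, 3L)), k * Fin, Fout)
  y <- X2 %*% Wm
  y <- y + rep(b, each = N * T)
  list(y = as_arr(y, N, T),
       cache = list(X2 = X2, Wm = Wm, N = N, T = T, Fin = Fin, k = k,
                    pad = pad))
}

conv1d_bw <- function(dy, cache) {
  N <- cache$N; T <- cache$T; Fin <- cache$Fin
  k <- cache$k; pad <- cache$pad
  dym <- as_mat(dy)
  db <- colSums(dym)
  dWm <- crossprod(cache$X2, dym)                  # (k*Fin, Fout)
  dW <- aperm(array(dWm, c(Fin, k, ncol(dym))), c(2L, 1L, 3L))
  dX2 <- dym %*% t(cache$Wm)                       # (N*T, k*Fin)
  dxp <- array(0, c(N, T + 2L * pad, Fin))
  for (j in seq_len(k)) {
    sl <- dX2[, ((j - 1L) * Fin + 1L):(j * Fin), drop = FALSE]
    dim(sl) <- c(N, T, Fin)
    rng <- j:(j + T - 1L)
    dxp[, rng, ] <- dxp[, rng, , drop = FALSE] + sl
  }
  list(dx = dxp[, (pad + 1L):(pad + T), , drop = FALSE], dW = dW, db = db)
}

# Max-pool along time, factor 2. Ties resolve to the earlier timestep.
maxpool2_fw <- function(x) {
  d <- dim(x); T <- d[2]
  stopifnot(T %% 2L == 0L)
  x1 <- x[, seq.int(1L, T, 2L), , drop = FALSE]
  x2 <- x[, seq.int(2L, T, 2L), , drop = FALSE]
  mask <- x1 >= x2
  list(y = pmax(x1, x2), cache = list(mask = mask, T = T))
}

maxpool2_bw <- function(dy, cache) {
  d <- dim(dy)
  dx <- array(0, c(d[1], cache$T, d[3]))
  dx[, seq.int(1L, cache$T, 2L), ] <- dy * cache$mask
  dx[, seq.int(2L, cache$T, 2L), ] <- dy * !cache$mask
  dx
}

# Stride-2 transposed convolution (kernel k, "same"-padded conv of the
# zero-stuffed input), so each stage exactly doubles the temporal length.
deconv2_fw <- function(x, W, b) {
  d <- dim(x); N <- d[1]; T <- d[2]
  z <- array(0, c(N, 2L * T, d[3]))
  z[, seq.int(1L, 2L * T, 2L), ] <- x
  cv <- conv1d_fw(z, W, b)
  list(y = cv$y, cache = cv$cache)
}

deconv2_bw <- function(dy, cache) {
  g <- conv1d_bw(dy, cache)
  list(dx = g$dx[, seq.int(1L, cache$T, 2L), , drop = FALSE],
       dW = g$dW, db = g$db)
}

# Batch normalization over rows of an (M, F) matrix; trainable scale/shift,
# running moments for inference mode.
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.99

bn_fw <- function(x, gamma, beta, state, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    state$mean <- BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * mu
    state$var <- BN_MOMENTUM * state$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, state = state,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training))
}

bn_bw <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dyg <- sweep(dy, 2L, cache$gamma, "*")
  if (cache$training) {
    dx <- sweep(dyg, 2L, colMeans(dyg), "-") -
      sweep(xhat, 2L, colMeans(dyg * xhat), "*")
    dx <- sweep(dx, 2L, cache$invstd, "*")
  } else {
    dx <- sweep(dyg, 2L, cache$invstd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_fw <- function(x, W, b) {
  list(y = sweep(x %*% W, 2L, b, "+"), cache = list(x = x, W = W))
}

dense_bw <- function(dy, cache) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# Numerically stabilized softmax over rows.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
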