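# Neural-network primitives on batch-first arrays. Feature maps are 3D arrays
# (batch, time, channels); heavy lifting is delegated to BLAS via im2col +
# matrix multiplication. Every op has a matching backward pass; correctness is
# pinned by numeric-gradient tests.

sigm <- function(x) 1 / (1 + exp(-x))

# --- 1D convolution (valid padding, stride 1) --------------------------------

# unfold (b, Tin, Cin) into (b*Tout, k*Cin); column block j holds offset j
im2col1d <- function(a, k) {
  d <- dim(a)
  tout <- d[2] - k + 1L
  m <- matrix(0, d[1] * tout, k * d[3])
  for (j in seq_len(k)) {
    m[, ((j - 1) * d[3] + 1):(j * d[3])] <-
      matrix(a[, j:(j + tout - 1), , drop = FALSE], d[1] * tout, d[3])
  }
  m
}

# scatter-add the im2col gradient back onto the input array
col2im1d <- function(dm, dims_in, k) {
  b <- dims_in[1]; cin <- dims_in[3]
  tout <- dims_in[2] - k + 1L
  da <- array(0, dims_in)
  for (j in seq_len(k)) {
    da[, j:(j + tout - 1), ] <- da[, j:(j + tout - 1), , drop = FALSE] +
      array(dm[, ((j - 1) * cin + 1):(j * cin)], c(b, tout, cin))
  }
  da
}

conv1d_forward <- function(a, w, bias) {
  k <- nrow(w) / dim(a)[3]
  m <- im2col1d(a, k)
  z <- sweep(m %*% w, 2, bias, "+")
  tout <- dim(a)[2] - k + 1L
  list(out = array(z, c(dim(a)[1], tout, ncol(w))), m = m, dims_in = dim(a), k = k)
}

conv1d_backward <- function(cache, w, dout) {
  d <- dim(dout)
  dz <- matrix(dout, d[1] * d[2], d[3])
  list(dw = crossprod(cache$m, dz),
       db = colSums(dz),
       da = col2im1d(dz %*% t(w), cache$dims_in, cache$k))
}

# --- max pooling (non-overlapping, floor semantics) --------------------------

maxpool_forward <- function(a, pool) {
  d <- dim(a)
  tout <- d[2] %/% pool
  vals <- a[, seq(1, by = pool, length.out = tout), , drop = FALSE]
  arg <- array(1L, c(d[1], tout, d[3]))
  if (pool > 1) {
    for (o in 2:pool) {
      cand <- a[, seq(o, by = pool, length.out = tout), , drop = FALSE]
      better <- cand > vals
      vals[better] <- cand[better]
      arg[better] <- o
    }
  }
  list(out = vals, arg = arg, dims_in = d, pool = pool)
}

maxpool_backward <- function(cache, dout) {
  da <- array(0, cache$dims_in)
  tout <- dim(dout)[2]
  for (o in seq_len(cache$pool)) {
    mask <- cache$arg == o
    slice <- array(0, dim(dout))
    slice[mask] <- dout[mask]
    idx <- seq(o, by = cache$pool, length.out = tout)
    da[, idx, ] <- da[, idx, , drop = FALSE] + slice
  }
  da
}

# --- elementwise layers ------------------------------------------------------

relu_forward <- function(a) {
  mask <- a > 0
  out <- a
  out[!mask] <- 0
  list(out = out, mask = mask)
}

relu_backward <- function(cache, dout) {
  dout[!cache$mask] <- 0
  dout
}

# inverted dropout; identity at inference
dropout_forward <- function(a, rate, training) {
  if (!training || rate <= 0) return(list(out = a, mask = NULL))
  mask <- array(stats::runif(length(a)) >= rate, dim = dim(a) %||% length(a)) /
    (1 - rate)
  list(out = a * mask, mask = mask)
}

dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# --- dense + softmax ---------------------------------------------------------

dense_forward <- function(x, w, bias) {
  list(out = sweep(x %*% w, 2, bias, "+"), x = x)
}

dense_backward <- function(cache, w, dout) {
  list(dw = crossprod(cache$x, dout), db = colSums(dout), dx = dout %*% t(w))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy loss and its gradient wrt the pre-softmax logits
softmax_xent <- function(z, y_onehot) {
  p <- softmax(z)
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(p + eps)))
  list(loss = loss, dz = (p - y_onehot) / nrow(z), p = p)
}

# --- batch normalization (per-feature, on 2D activations) --------------------

batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.9, eps = 1e-3,
                              init_running = FALSE) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    if (init_running) {
      # seed the running statistics from the first batch: with few updates
      # per epoch the default (0, 1) start would leave inference activations
      # on a different scale than training for many epochs
      run_mean <- mu
      run_var <- v
    } else {
      run_mean <- momentum * run_mean + (1 - momentum) * mu
      run_var <- momentum * run_var + (1 - momentum) * v
    }
  } else {
    mu <- run_mean; v <- run_var
  }
  xc <- sweep(x, 2, mu)
  inv_sd <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, inv_sd, "*")
  out <- sweep(sweep(xn, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xn = xn, xc = xc, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(cache, gamma, dout) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xn)
  dbeta <- colSums(dout)
  dxn <- sweep(dout, 2, gamma, "*")
  # standard batch-norm gradient
  dx <- sweep(dxn - matrix(colMeans(dxn), n, ncol(dxn), byrow = TRUE) -
                sweep(cache$xn, 2, colMeans(dxn * cache$xn), "*"),
              2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- LSTM (single layer, final state only) -----------------------------------
# Gate order i, f, g (cell candidate), o. Two independent bias vectors (input
# path and recurrent path) are kept, so the parameter count is
# 4u(Cin + u) + 2*4u.

lstm_forward <- function(x, p, keep_cache = TRUE) {
  d <- dim(x) # (b, T, Cin)
  b <- d[1]; steps <- d[2]
  u <- nrow(p$Wh)
  h <- matrix(0, b, u); cs <- matrix(0, b, u)
  bias <- p$bx + p$bh
  cache <- if (keep_cache) vector("list", steps)
  for (t in seq_len(steps)) {
    xt <- matrix(x[, t, ], b, d[3])
    z <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, bias, "+")
    i <- sigm(z[, 1:u, drop = FALSE])
    f <- sigm(z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h_prev <- h
    h <- o * tc
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, tc = tc)
  }
  list(out = h, cache = cache, dims_in = d)
}

lstm_backward <- function(fw, p, dh_last) {
  dWx <- 0 * p$Wx; dWh <- 0 * p$Wh; db <- 0 * p$bx
  dh <- dh_last
  dc <- 0 * dh_last
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(p$Wh)
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, bx = db, bh = db)
}

# --- convLSTM (1 x k kernel over a 1 x S spatial grid) -----------------------
# Input conv uses valid padding (S -> S-k+1); the recurrent conv on the hidden
# state uses same padding. Single bias per gate:
# params = 4u * (k*Cin + k*u + 1).

pad_time <- function(a, pad) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  out[, (pad + 1):(pad + d[2]), ] <- a
  out
}

convlstm_forward <- function(x, p, k, keep_cache = TRUE) {
  d <- dim(x) # (b, steps, S, Cin)
  b <- d[1]; steps <- d[2]; s_in <- d[3]
  u <- length(p$b) / 4
  s_out <- s_in - k + 1L
  pad <- (k - 1L) %/% 2L
  h <- array(0, c(b, s_out, u))
  cs <- array(0, c(b, s_out, u))
  cache <- if (keep_cache) vector("list", steps)
  for (t in seq_len(steps)) {
    xt <- array(x[, t, , ], c(b, s_in, d[4]))
    mx <- im2col1d(xt, k)
    mh <- im2col1d(pad_time(h, pad), k)
    z <- sweep(mx %*% p$Wx + mh %*% p$Wh, 2, p$b, "+") # (b*s_out, 4u)
    zi <- array(z, c(b, s_out, 4 * u))
    i <- sigm(zi[, , 1:u, drop = FALSE])
    f <- sigm(zi[, , (u + 1):(2 * u), drop = FALSE])
    g <- tanh(zi[, , (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm(zi[, , (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h_prev <- h
    h <- o * tc
    if (keep_cache)
      cache[[t]] <- list(mx = mx, mh = mh, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, tc = tc)
  }
  list(out = h, cache = cache, dims_in = d, s_out = s_out, pad = pad, k = k)
}

convlstm_backward <- function(fw, p, dh_last) {
  d <- fw$dims_in
  b <- d[1]; s_out <- fw$s_out
  u <- length(p$b) / 4
  dWx <- 0 * p$Wx; dWh <- 0 * p$Wh; db <- 0 * p$b
  dh <- dh_last
  dc <- 0 * dh_last
  h_dims_padded <- c(b, s_out + 2 * fw$pad, u)
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- array(0, c(b, s_out, 4 * u))
    dz[, , 1:u] <- di * cc$i * (1 - cc$i)
    dz[, , (u + 1):(2 * u)] <- df * cc$f * (1 - cc$f)
    dz[, , (2 * u + 1):(3 * u)] <- dg * (1 - cc$g^2)
    dz[, , (3 * u + 1):(4 * u)] <- do_ * cc$o * (1 - cc$o)
    dzm <- matrix(dz, b * s_out, 4 * u)
    dWx <- dWx + crossprod(cc$mx, dzm)
    dWh <- dWh + crossprod(cc$mh, dzm)
    db <- db + colSums(dzm)
    dpad <- col2im1d(dzm %*% t(p$Wh), h_dims_padded, fw$k)
    dh <- dpad[, (fw$pad + 1):(fw$pad + s_out), , drop = FALSE]
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# --- initialization ----------------------------------------------------------

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
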