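# Low-level neural-network layers on [channels x time x batch] arrays, with
# explicit reverse-mode gradients. All layers are plain R; gradient
# correctness is verified against central finite differences in the tests.
# Initialization follows the usual fan-in uniform scheme
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)).

init_conv <- function(c_out, c_in, k) {
  lim <- 1 / sqrt(c_in * k)
  list(W = array(runif(c_out * c_in * k, -lim, lim), c(c_out, c_in, k)),
       b = runif(c_out, -lim, lim))
}

init_linear <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  list(W = matrix(runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = runif(d_out, -lim, lim))
}

# --- dilated causal 1D convolution (left padding == conv + chomp) ----------
# x [Cin x T x N], W [Cout x Cin x k]. Output [Cout x T x N]; y[, t, ] uses
# x[, t - (k - tap) * dilation, ] for taps 1..k, so only past/present inputs.

conv1d_forward <- function(x, W, b, dilation) {
  d <- dim(x); Cin <- d[1]; T <- d[2]; N <- d[3]
  kd <- dim(W); Cout <- kd[1]; k <- kd[3]
  stopifnot(kd[2] == Cin)
  pad <- (k - 1L) * dilation
  xp <- array(0, c(Cin, T + pad, N))
  xp[, pad + seq_len(T), ] <- x
  ymat <- matrix(0, Cout, T * N)
  for (tap in seq_len(k)) {
    off <- (tap - 1L) * dilation
    xs <- xp[, off + seq_len(T), , drop = FALSE]
    dim(xs) <- c(Cin, T * N)
    ymat <- ymat + matrix(W[, , tap], Cout, Cin) %*% xs
  }
  ymat <- ymat + b
  array(ymat, c(Cout, T, N))
}

conv1d_backward <- function(dy, x, W, dilation) {
  d <- dim(x); Cin <- d[1]; T <- d[2]; N <- d[3]
  kd <- dim(W); Cout <- kd[1]; k <- kd[3]
  pad <- (k - 1L) * dilation
  xp <- array(0, c(Cin, T + pad, N))
  xp[, pad + seq_len(T), ] <- x
  dymat <- dy; dim(dymat) <- c(Cout, T * N)
  dW <- array(0, dim(W))
  dxp <- array(0, c(Cin, T + pad, N))
  for (tap in seq_len(k)) {
    off <- (tap - 1L) * dilation
    xs <- xp[, off + seq_len(T), , drop = FALSE]
    dim(xs) <- c(Cin, T * N)
    dW[, , tap] <- tcrossprod(dymat, xs)
    dxs <- crossprod(matrix(W[, , tap], Cout, Cin), dymat)
    dim(dxs) <- c(Cin, T, N)
    dxp[, off + seq_len(T), ] <-
      dxp[, off + seq_len(T), , drop = FALSE] + dxs
  }
  list(dx = dxp[, pad + seq_len(T), , drop = FALSE],
       dW = dW, db = rowSums(dymat))
}

# --- batch normalization over (time, batch) per channel --------------------

bn_forward <- function(x, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x); C <- d[1]; m <- d[2] * d[3]
  xm <- x; dim(xm) <- c(C, m)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    state$run_mean <- (1 - momentum) * state$run_mean + momentum * mu
    # unbiased running variance, as torch does
    state$run_var <- (1 - momentum) * state$run_var +
      momentum * v * m / max(m - 1, 1)
  } else {
    mu <- state$run_mean
    v <- state$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, state = state)
}

bn_backward <- function(dy, cache, gamma, training) {
  d <- dim(dy); C <- d[1]; m <- d[2] * d[3]
  dym <- dy; dim(dym) <- c(C, m)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  if (training) {
    dx <- cache$inv / m *
      (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- elementwise ----------------------------------------------------------

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dy, x) dy * (x > 0)

dropout_mask <- function(dims, p) {
  array((runif(prod(dims)) >= p) / (1 - p), dims)
}
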