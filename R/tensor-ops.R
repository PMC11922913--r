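# Internal tensor primitives for the residual depth-wise network.
#
# Activations are stored as arrays of dim (H, W, C, N) — column-major, sample
# outermost — so pointwise convolutions and the dense head reduce to BLAS GEMM
# calls and spatial convolutions go through im2col + GEMM.  All convolutions
# are stride 1 (the architecture uses no strided layers), which keeps the
# input-gradient as a full convolution with the spatially flipped kernel.

zero_pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

# column matrix of receptive fields: rows ordered (row, col, sample),
# columns ordered (k_row, k_col, channel) to match dim(W) = (kh, kw, Cin, Cout)
im2col <- function(xp, kh, kw, Hout, Wout) {
  d <- dim(xp); Hp <- d[1]; Wp <- d[2]; C <- d[3]; N <- d[4]
  pos <- as.vector(outer(0:(Hout - 1), (0:(Wout - 1)) * Hp, "+"))
  off <- as.vector(outer(as.vector(outer(0:(kh - 1), (0:(kw - 1)) * Hp, "+")),
                         (0:(C - 1)) * Hp * Wp, "+"))
  idx <- outer(pos, off, "+") + 1L
  P <- Hout * Wout
  cols <- matrix(0, P * N, kh * kw * C)
  stride <- Hp * Wp * C
  for (n in seq_len(N)) {
    cols[((n - 1L) * P + 1L):(n * P), ] <- xp[idx + (n - 1L) * stride]
  }
  cols
}

# y (P*N, Cout) with rows ordered (row, col, sample) -> array (Hout, Wout, Cout, N)
fold_output <- function(y, Hout, Wout, N) {
  Cout <- ncol(y)
  aperm(array(y, c(Hout, Wout, N, Cout)), c(1, 2, 4, 3))
}

unfold_grad <- function(dy) {
  d <- dim(dy)
  matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

conv2d_forward <- function(x, W, b, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  d <- dim(x); N <- d[4]
  if (kh == 1L && kw == 1L && pad == 0L) {
    xm <- unfold_grad(x)                        # (H*W*N, Cin)
    y <- xm %*% matrix(W, dim(W)[3], Cout)
    y <- sweep(y, 2, b, "+")
    return(list(out = fold_output(y, d[1], d[2], N), cols = xm,
                Hout = d[1], Wout = d[2], pad = 0L))
  }
  Hout <- d[1] + 2L * pad - kh + 1L
  Wout <- d[2] + 2L * pad - kw + 1L
  xp <- zero_pad_hw(x, pad)
  cols <- im2col(xp, kh, kw, Hout, Wout)
  y <- cols %*% matrix(W, kh * kw * d[3], Cout)
  y <- sweep(y, 2, b, "+")
  list(out = fold_output(y, Hout, Wout, N), cols = cols,
       Hout = Hout, Wout = Wout, pad = pad)
}

conv2d_backward <- function(dy, x, W, cache) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  dym <- unfold_grad(dy)
  dW <- array(crossprod(cache$cols, dym), dim(W))
  db <- colSums(dym)
  # input gradient: full convolution with flipped, channel-transposed kernel
  Wf <- aperm(W[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
  pad_b <- kh - 1L - cache$pad
  dx <- conv2d_forward(dy, Wf, numeric(Cin), pad_b)$out
  list(dx = dx, dW = dW, db = db)
}

depthwise_forward <- function(x, W, b, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  d <- dim(x); C <- d[3]; N <- d[4]
  Hout <- d[1] + 2L * pad - kh + 1L
  Wout <- d[2] + 2L * pad - kw + 1L
  xp <- zero_pad_hw(x, pad)
  out <- array(0, c(Hout, Wout, C, N))
  for (dr in seq_len(kh)) {
    for (dc in seq_len(kw)) {
      slice <- xp[dr:(dr + Hout - 1L), dc:(dc + Wout - 1L), , , drop = FALSE]
      out <- out + slice * rep(W[dr, dc, ], each = Hout * Wout)
    }
  }
  out + rep(b, each = Hout * Wout)
}

depthwise_backward <- function(dy, x, W, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  d <- dim(x); C <- d[3]; N <- d[4]
  Hout <- dim(dy)[1]; Wout <- dim(dy)[2]
  xp <- zero_pad_hw(x, pad)
  dW <- array(0, dim(W))
  for (dr in seq_len(kh)) {
    for (dc in seq_len(kw)) {
      slice <- xp[dr:(dr + Hout - 1L), dc:(dc + Wout - 1L), , , drop = FALSE]
      prod <- slice * dy
      dW[dr, dc, ] <- rowSums(matrix(colSums(matrix(prod, Hout * Wout, C * N)), C, N))
    }
  }
  db <- rowSums(matrix(colSums(matrix(dy, Hout * Wout, C * N)), C, N))
  # full depthwise convolution of dy with the flipped kernel
  Wf <- W[kh:1, kw:1, , drop = FALSE]
  dx <- depthwise_forward(dy, Wf, numeric(C), kh - 1L - pad)
  list(dx = dx, dW = dW, db = db)
}

batchnorm_forward <- function(x, gamma, beta, running_mean, running_var,
                              train, eps = 1e-5, momentum = 0.9) {
  d <- dim(x); C <- d[3]
  m <- d[1] * d[2] * d[4]
  xm <- unfold_grad(x)                          # (m, C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running_mean <- momentum * running_mean + (1 - momentum) * mu
    running_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = fold_output(y, d[1], d[2], d[4]),
       xhat = xhat, ivar = ivar,
       running_mean = running_mean, running_var = running_var)
}

batchnorm_backward <- function(dy, gamma, cache) {
  d <- dim(dy); m <- d[1] * d[2] * d[4]
  dym <- unfold_grad(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2, dbeta / m, "-")
  t2 <- sweep(xhat, 2, dgamma / m, "*")
  dxm <- sweep(t1 - t2, 2, gamma * cache$ivar, "*")
  list(dx = fold_output(dxm, d[1], d[2], d[4]), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x, k = 2L) {
  d <- dim(x)
  Hout <- d[1] %/% k; Wout <- d[2] %/% k
  ri <- seq_len(Hout * k); ci <- seq_len(Wout * k)
  xs <- x[ri, ci, , , drop = FALSE]
  out <- array(-Inf, c(Hout, Wout, d[3], d[4]))
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      out <- pmax(out, xs[seq(dr, by = k, length.out = Hout),
                          seq(dc, by = k, length.out = Wout), , , drop = FALSE])
    }
  }
  out
}

maxpool_backward <- function(dy, x, k = 2L) {
  d <- dim(x)
  Hout <- dim(dy)[1]; Wout <- dim(dy)[2]
  out <- maxpool_forward(x, k)
  dx <- array(0, d)
  taken <- array(FALSE, dim(dy))
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      rs <- seq(dr, by = k, length.out = Hout)
      cs <- seq(dc, by = k, length.out = Wout)
      hit <- (x[rs, cs, , , drop = FALSE] == out) & !taken
      dx[rs, cs, , ] <- dx[rs, cs, , , drop = FALSE] + dy * hit
      taken <- taken | hit
    }
  }
  dx
}

relu_fwd <- function(x) pmax(x, 0)
sigmoid_fwd <- function(z) 1 / (1 + exp(-z))
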