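# Low-level differentiable tensor operations.
#
# Tensors are base-R arrays laid out (H, W, C, B): rows, columns, channels,
# batch. Every *_forward returns list(out, cache); the matching *_backward
# takes the upstream gradient and the cache and returns the input gradient
# plus parameter gradients. Convolutions use same padding in the
# ceil(size/stride) convention.

bn_eps <- 1e-5

# ---- activations -----------------------------------------------------------

#' Swish activation
#'
#' The smooth, non-monotonic activation `v * sigmoid(v)` used between the
#' convolutional stages.
#'
#' @param v numeric vector/array.
#' @return `v * sigmoid(v)`, same shape.
#' @export
swish <- function(v) v * sigmoid(v)

act_forward <- function(x, kind) {
  out <- switch(kind,
                swish = swish(x),
                relu = pmax(x, 0),
                leaky_relu = ifelse(x > 0, x, 0.01 * x))
  list(out = out, cache = x)
}

act_backward <- function(dout, cache, kind) {
  x <- cache
  d <- switch(kind,
              swish = { s <- sigmoid(x); s * (1 + x * (1 - s)) },
              relu = (x > 0) + 0,
              leaky_relu = ifelse(x > 0, 1, 0.01))
  dout * d
}

# ---- full convolution (im2col) --------------------------------------------

conv_geometry <- function(H, W, C, M, N, stride) {
  OH <- ceiling(H / stride); OW <- ceiling(W / stride)
  ph <- max((OH - 1) * stride + M - H, 0)
  pw <- max((OW - 1) * stride + N - W, 0)
  Hp <- H + ph; Wp <- W + pw
  oi <- rep(seq_len(OH), times = OW)
  oj <- rep(seq_len(OW), each = OH)
  m <- rep(seq_len(M), times = N * C)
  n <- rep(rep(seq_len(N), each = M), times = C)
  cc <- rep(seq_len(C), each = M * N)
  r <- outer((oi - 1) * stride, m, `+`)
  cl <- outer((oj - 1) * stride, n, `+`)
  idx <- r + (cl - 1) * Hp +
    matrix(rep((cc - 1) * Hp * Wp, each = OH * OW), nrow = OH * OW)
  list(OH = OH, OW = OW, Hp = Hp, Wp = Wp,
       pt = ph %/% 2, pl = pw %/% 2, idx = idx)
}

pad_input <- function(x, g) {
  d <- dim(x)
  Xp <- array(0, c(g$Hp, g$Wp, d[3], d[4]))
  Xp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , ] <- x
  Xp
}

# x: (H,W,C,B); Q: (M,N,C,K); b: length-K bias or NULL
conv2d_forward <- function(x, Q, b = NULL, stride = 1) {
  d <- dim(x); dq <- dim(Q)
  if (d[3] != dq[3]) stopf("conv2d: input has %d channels, kernel expects %d",
                           d[3], dq[3])
  g <- conv_geometry(d[1], d[2], d[3], dq[1], dq[2], stride)
  Xp <- pad_input(x, g)
  dim(Xp) <- c(g$Hp * g$Wp * d[3], d[4])
  P <- g$OH * g$OW; Kc <- prod(dq[1:3]); K <- dq[4]; B <- d[4]
  cols <- Xp[as.vector(g$idx), , drop = FALSE]        # (P*Kc, B)
  dim(cols) <- c(P, Kc, B)
  cols <- aperm(cols, c(1, 3, 2))
  dim(cols) <- c(P * B, Kc)
  Wm <- Q; dim(Wm) <- c(Kc, K)
  om <- cols %*% Wm
  if (!is.null(b)) om <- sweep(om, 2, b, `+`)
  out <- array(om, c(g$OH, g$OW, B, K))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out,
       cache = list(cols = cols, g = g, din = d, dq = dq, stride = stride))
}

conv2d_backward <- function(dout, Q, cache) {
  g <- cache$g; d <- cache$din; dq <- cache$dq
  P <- g$OH * g$OW; Kc <- prod(dq[1:3]); K <- dq[4]; B <- d[4]
  dm <- aperm(dout, c(1, 2, 4, 3))                    # (OH,OW,B,K)
  dim(dm) <- c(P * B, K)
  dW <- crossprod(cache$cols, dm)                     # (Kc, K)
  dim(dW) <- dq
  db <- colSums(dm)
  Wm <- Q; dim(Wm) <- c(Kc, K)
  dcols <- dm %*% t(Wm)                               # (P*B, Kc)
  dim(dcols) <- c(P, B, Kc)
  dcols <- aperm(dcols, c(1, 3, 2))
  dim(dcols) <- c(P * Kc, B)
  rs <- rowsum(dcols, group = as.vector(g$idx))
  dXp <- matrix(0, g$Hp * g$Wp * d[3], B)
  dXp[as.integer(rownames(rs)), ] <- rs
  dim(dXp) <- c(g$Hp, g$Wp, d[3], B)
  dx <- dXp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

#' 2-D convolution of a feature map
#'
#' Direct evaluation of the convolutional stem equation: each output
#' channel k is `y(i,j,k) = sum_{m,n,c} x(i+m, j+n, c) Q(m,n,c,k) + B(k)`
#' with same padding, output spatial dims `ceiling(input / stride)`.
#'
#' @param x feature map, array `(H, W, C)` or `(H, W, C, B)`.
#' @param kernel list with `Q`, an `(M, N, C, K)` weight array, and
#'   optional bias `b` of length K.
#' @param stride positive integer stride.
#' @return convolved feature map, same batch layout as the input.
#' @export
conv2d <- function(x, kernel, stride = 1) {
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x), 1)
  out <- conv2d_forward(x, kernel$Q, kernel$b, stride)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

# ---- pointwise (1x1, stride 1) convolution --------------------------------

conv1x1_forward <- function(x, W, stride = 1) {   # W: (Cin, K)
  if (stride != 1) {
    Q <- array(W, c(1, 1, nrow(W), ncol(W)))
    return(conv2d_forward(x, Q, NULL, stride))
  }
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  om <- xm %*% W
  out <- array(om, c(d[1], d[2], d[4], ncol(W)))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(xm = xm, din = d))
}

conv1x1_backward <- function(dout, W, cache) {
  d <- cache$din
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(d[1] * d[2] * d[4], ncol(W))
  dW <- crossprod(cache$xm, dm)
  dxm <- dm %*% t(W)
  dx <- array(dxm, c(d[1], d[2], d[4], d[3]))
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dW = dW)
}

# ---- depthwise 3x3 convolution --------------------------------------------

# W: (M, N, C) — one spatial kernel per channel.
depthwise_forward <- function(x, W, stride = 1) {
  d <- dim(x); M <- dim(W)[1]; N <- dim(W)[2]
  g <- conv_geometry(d[1], d[2], d[3], M, N, stride)
  Xp <- pad_input(x, g)
  out <- array(0, c(g$OH, g$OW, d[3], d[4]))
  for (m in seq_len(M)) for (n in seq_len(N)) {
    rows <- (seq_len(g$OH) - 1) * stride + m
    cols <- (seq_len(g$OW) - 1) * stride + n
    slice <- Xp[rows, cols, , , drop = FALSE]
    out <- out + slice * rep(W[m, n, ], each = g$OH * g$OW)
  }
  list(out = out, cache = list(Xp = Xp, g = g, din = d, stride = stride))
}

depthwise_backward <- function(dout, W, cache) {
  g <- cache$g; d <- cache$din
  M <- dim(W)[1]; N <- dim(W)[2]; stride <- cache$stride
  dW <- array(0, dim(W))
  dXp <- array(0, dim(cache$Xp))
  for (m in seq_len(M)) for (n in seq_len(N)) {
    rows <- (seq_len(g$OH) - 1) * stride + m
    cols <- (seq_len(g$OW) - 1) * stride + n
    slice <- cache$Xp[rows, cols, , , drop = FALSE]
    tmp <- dout * slice
    dim(tmp) <- c(g$OH * g$OW, d[3] * d[4])
    dW[m, n, ] <- rowSums(matrix(colSums(tmp), d[3], d[4]))
    dXp[rows, cols, , ] <- dXp[rows, cols, , , drop = FALSE] +
      dout * rep(W[m, n, ], each = g$OH * g$OW)
  }
  dx <- dXp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW)
}

# ---- batch normalization (per channel over H, W, B) -----------------------

bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       training = TRUE, momentum = 0.9) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  ivar <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, `*`)
  om <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- array(om, c(d[1], d[2], d[4], d[3]))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, din = d,
                    training = training))
}

bn_backward <- function(dout, cache) {
  d <- cache$din
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, cache$gamma, `*`)
  if (cache$training) {
    Nn <- nrow(dm)
    dxm <- sweep(dxhat -
                   matrix(colMeans(dxhat), Nn, ncol(dm), byrow = TRUE) -
                   sweep(cache$xhat, 2,
                         colMeans(dxhat * cache$xhat), `*`),
                 2, cache$ivar, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cache$ivar, `*`)
  }
  dx <- array(dxm, c(d[1], d[2], d[4], d[3]))
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- squeeze and excitation -----------------------------------------------

se_forward <- function(x, W1, b1, W2, b2, activation = "swish") {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2], d[4] * d[3])
  z <- matrix(colMeans(xm), d[4], d[3])              # (B, C) channel means
  z <- t(z)                                          # (C, B)
  a1 <- W1 %*% z + b1                                # (Cr, B)
  h1 <- act_forward(a1, activation)
  a2 <- W2 %*% h1$out + b2                           # (C, B)
  gate <- sigmoid(a2)
  gx <- aperm(array(rep(as.vector(gate), each = d[1] * d[2]),
                    c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))
  out <- x * gx
  list(out = out,
       cache = list(x = x, z = z, a1cache = h1$cache, h1 = h1$out,
                    gate = gate, W1 = W1, W2 = W2, din = d,
                    activation = activation))
}

se_backward <- function(dout, cache) {
  d <- cache$din
  gate4 <- array(rep(as.vector(cache$gate), each = d[1] * d[2]),
                 c(d[1], d[2], d[3], d[4]))
  dx_direct <- dout * gate4
  # gradient wrt the gate, pooled over space
  tmp <- dout * cache$x
  dim(tmp) <- c(d[1] * d[2], d[3] * d[4])
  dgate <- matrix(colSums(tmp), d[3], d[4])          # (C, B)
  da2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- da2 %*% t(cache$h1)
  db2 <- rowSums(da2)
  dh1 <- t(cache$W2) %*% da2
  da1 <- act_backward(dh1, cache$a1cache, cache$activation)
  dW1 <- da1 %*% t(cache$z)
  db1 <- rowSums(da1)
  dz <- t(cache$W1) %*% da1                          # (C, B)
  dx_pool <- array(rep(as.vector(dz), each = d[1] * d[2]),
                   c(d[1], d[2], d[3], d[4])) / (d[1] * d[2])
  list(dx = dx_direct + dx_pool,
       dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Squeeze-and-excitation gating
#'
#' Channelwise recalibration: global average pooling squeezes each channel
#' to a scalar, a two-layer bottleneck with sigmoid output produces a gate
#' in (0, 1) per channel, and every channel is multiplied by its gate.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, B)`.
#' @param params list with `W1` (Cr x C), `b1`, `W2` (C x Cr), `b2`.
#' @param activation hidden activation of the bottleneck.
#' @return the recalibrated feature map.
#' @export
se_block <- function(x, params, activation = "swish") {
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x), 1)
  out <- se_forward(x, params$W1, params$b1, params$W2, params$b2,
                    activation)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

# ---- LSTM ------------------------------------------------------------------

# xs: (D, T, B) sequence of step vectors. Gates ordered i, f, g, o.
lstm_forward <- function(xs, Wx, Wh, b) {
  D <- dim(xs)[1]; T <- dim(xs)[2]; B <- dim(xs)[3]
  H <- nrow(Wx) / 4
  h <- matrix(0, H, B); cst <- matrix(0, H, B)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- matrix(xs[, t, ], D, B)
    zt <- Wx %*% xt + Wh %*% h + b
    i <- sigmoid(zt[seq_len(H), , drop = FALSE])
    f <- sigmoid(zt[H + seq_len(H), , drop = FALSE])
    gg <- tanh(zt[2 * H + seq_len(H), , drop = FALSE])
    o <- sigmoid(zt[3 * H + seq_len(H), , drop = FALSE])
    c_new <- f * cst + i * gg
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cst,
                       i = i, f = f, g = gg, o = o, c_new = c_new, tc = tc)
    h <- h_new; cst <- c_new
  }
  list(out = h, cache = list(steps = steps, D = D, T = T, B = B, H = H,
                             Wx = Wx, Wh = Wh))
}

lstm_backward <- function(dh_final, cache) {
  D <- cache$D; T <- cache$T; B <- cache$B; H <- cache$H
  dWx <- matrix(0, 4 * H, D); dWh <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  dxs <- array(0, c(D, T, B))
  dh <- dh_final; dc <- matrix(0, H, B)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dzi <- di * st$i * (1 - st$i)
    dzf <- df * st$f * (1 - st$f)
    dzg <- dg * (1 - st$g^2)
    dzo <- do * st$o * (1 - st$o)
    dz <- rbind(dzi, dzf, dzg, dzo)
    dWx <- dWx + dz %*% t(st$xt)
    dWh <- dWh + dz %*% t(st$h_prev)
    db <- db + rowSums(dz)
    dxs[, t, ] <- t(cache$Wx) %*% dz
    dh <- t(cache$Wh) %*% dz
    dc <- dc * st$f
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# ---- dense + softmax -------------------------------------------------------

dense_forward <- function(x, W, b) {               # x: (Din, B)
  list(out = W %*% x + b, cache = x)
}

dense_backward <- function(dout, W, cache) {
  list(dx = t(W) %*% dout, dW = dout %*% t(cache), db = rowSums(dout))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# cross-entropy on logits (K, B) with integer class labels y (1-based)
softmax_ce <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(p)
  idx <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / B)
}
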