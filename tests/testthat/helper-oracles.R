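# Independent brute-force oracles used to validate the package's
# vectorized implementations, plus small shared fixtures.

# Sliding least-squares polynomial smoother: explicit normal equations per
# window, interior points only (returns NA at the edges).
savgol_oracle <- function(x, window, order) {
  h <- (window - 1) / 2
  out <- rep(NA_real_, length(x))
  t <- -h:h
  A <- outer(t, 0:order, `^`)
  for (i in (h + 1):(length(x) - h)) {
    beta <- solve(crossprod(A), crossprod(A, x[(i - h):(i + h)]))
    out[i] <- beta[1]          # polynomial value at the window centre
  }
  out
}

# Naive quadruple-loop 2-D convolution with same padding in the
# ceil(size/stride) convention: y(i,j,k) = sum x(i+m, j+n, c) Q(m,n,c,k) + b(k).
conv_oracle <- function(x, Q, b = NULL, stride = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  M <- dim(Q)[1]; N <- dim(Q)[2]; K <- dim(Q)[4]
  OH <- ceiling(H / stride); OW <- ceiling(W / stride)
  ph <- max((OH - 1) * stride + M - H, 0); pw <- max((OW - 1) * stride + N - W, 0)
  pt <- ph %/% 2; pl <- pw %/% 2
  xp <- array(0, c(H + ph, W + pw, C))
  xp[pt + seq_len(H), pl + seq_len(W), ] <- x
  out <- array(0, c(OH, OW, K))
  for (i in seq_len(OH)) for (j in seq_len(OW)) for (k in seq_len(K)) {
    acc <- 0
    for (m in seq_len(M)) for (n in seq_len(N)) for (c in seq_len(C))
      acc <- acc + xp[(i - 1) * stride + m, (j - 1) * stride + n, c] * Q[m, n, c, k]
    out[i, j, k] <- acc + if (is.null(b)) 0 else b[k]
  }
  out
}

# Depthwise variant: one spatial kernel per channel.
depthwise_oracle <- function(x, W, stride = 1) {
  C <- dim(x)[3]
  out <- NULL
  for (c in seq_len(C)) {
    Q <- array(W[, , c], c(dim(W)[1], dim(W)[2], 1, 1))
    oc <- conv_oracle(array(x[, , c], c(dim(x)[1], dim(x)[2], 1)), Q,
                      stride = stride)
    if (is.null(out)) out <- array(0, c(dim(oc)[1], dim(oc)[2], C))
    out[, , c] <- oc[, , 1]
  }
  out
}

# Small separable two-subject image set for augmentation / split tests.
tiny_gram_set <- function(n_subjects = 2, per_subject = 4, side = 12, seed = 42) {
  cfg <- generator_config(n_subjects = n_subjects,
                          signals_per_subject = per_subject,
                          signal_length = 120, noise_sd = 200, seed = seed)
  dataset_to_grams(build_dataset(cfg), "raw", side = side)
}

# Micro model configuration that trains in seconds.
micro_config <- function(n_classes, side = 16) {
  cfg <- model_config("tiny", n_classes = n_classes, input_side = side)
  cfg$stem_channels <- 4
  cfg$blocks <- list(list(t = 2, c = 8, s = 2), list(t = 2, c = 8, s = 1))
  cfg
}
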