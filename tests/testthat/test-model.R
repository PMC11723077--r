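test_that("convolution matches the naive quadruple-loop evaluation", {
  set.seed(21)
  for (case in 1:20) {
    H <- sample(4:7, 1); W <- sample(4:7, 1)
    C <- sample(1:3, 1); K <- sample(1:3, 1)
    stride <- sample(1:2, 1)
    x <- array(rnorm(H * W * C), c(H, W, C))
    Q <- array(rnorm(9 * C * K), c(3, 3, C, K))
    b <- rnorm(K)
    got <- conv2d(x, list(Q = Q, b = b), stride = stride)
    want <- conv_oracle(x, Q, b, stride)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("identity and bias-only kernels behave in closed form", {
  set.seed(22)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  Qid <- array(0, c(1, 1, 2, 2)); Qid[1, 1, 1, 1] <- 1; Qid[1, 1, 2, 2] <- 1
  expect_equal(conv2d(x, list(Q = Qid, b = c(0, 0))), x)

  Q0 <- array(0, c(3, 3, 2, 2))
  out <- conv2d(x, list(Q = Q0, b = c(1.5, -2)))
  expect_true(all(out[, , 1] == 1.5) && all(out[, , 2] == -2))

  expect_error(conv2d(x, list(Q = array(0, c(3, 3, 3, 1)))), "channels")
})

test_that("the depthwise stage matches its per-channel oracle", {
  set.seed(23)
  for (stride in 1:2) {
    x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
    W <- array(rnorm(9 * 4), c(3, 3, 4))
    got <- ppgid:::depthwise_forward(x, W, stride)$out[, , , 1]
    expect_lt(max(abs(got - depthwise_oracle(x[, , , 1], W, stride))), 1e-10)
  }
})

test_that("swish has its closed-form values and limits", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)))
  expect_lt(abs(swish(20) / 20 - 1), 1e-6)
})

test_that("squeeze-and-excitation gates channels as the equations state", {
  # constant channels: the squeeze is exactly the channel value and
  # zero-weight excitation gives gate sigmoid(0) = 1/2
  x <- array(0, c(4, 4, 3))
  vals <- c(0.2, -1, 3)
  for (c in 1:3) x[, , c] <- vals[c]
  C <- 3; Cr <- 2
  zero <- list(W1 = matrix(0, Cr, C), b1 = rep(0, Cr),
               W2 = matrix(0, C, Cr), b2 = rep(0, C))
  expect_equal(se_block(x, zero), x / 2)

  # large positive b2 drives the gate to 1: identity limit
  openg <- zero; openg$b2 <- rep(20, C)
  expect_equal(se_block(x, openg), x, tolerance = 1e-6)

  # gates always in (0, 1): output magnitude never exceeds input
  set.seed(24)
  xr <- array(rnorm(48), c(4, 4, 3))
  pr <- list(W1 = matrix(rnorm(6), 2, 3), b1 = rnorm(2),
             W2 = matrix(rnorm(6), 3, 2), b2 = rnorm(3))
  out <- se_block(xr, pr)
  expect_true(all(abs(out) <= abs(xr) + 1e-12))
  expect_error(se_block(xr, list(W1 = matrix(0, 2, 5), b1 = rep(0, 2),
                                 W2 = matrix(0, 5, 2), b2 = rep(0, 5))))
})

test_that("inverted-residual blocks keep the skip path and halve sides at stride 2", {
  set.seed(25)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  zero_block <- function(cin, cexp, cout, red) list(
    "exp.W" = matrix(0, cin, cexp), "exp.bn.g" = rep(0, cexp), "exp.bn.b" = rep(0, cexp),
    "dw.W" = array(0, c(3, 3, cexp)), "dw.bn.g" = rep(0, cexp), "dw.bn.b" = rep(0, cexp),
    "se.W1" = matrix(0, red, cexp), "se.b1" = rep(0, red),
    "se.W2" = matrix(0, cexp, red), "se.b2" = rep(0, cexp),
    "proj.W" = matrix(0, cexp, cout), "proj.bn.g" = rep(0, cout), "proj.bn.b" = rep(0, cout))
  # all-zero weights, residual-eligible: the skip connection survives
  expect_equal(mbconv(x, zero_block(6, 12, 6, 2), stride = 1), x)
  # stride 2 halves the spatial side
  out <- mbconv(x, zero_block(6, 12, 6, 2), stride = 2)
  expect_equal(dim(out), c(4, 4, 6))
})

test_that("feature extraction is a pure function with the documented shape", {
  cfg <- model_config("tiny", n_classes = 4)
  m <- build_model(cfg, seed = 3)
  set.seed(26)
  img <- matrix(runif(64 * 64), 64, 64)
  f1 <- extract_features(img, m)
  expect_equal(dim(f1), c(8, 8, 16, 1))
  expect_identical(f1, extract_features(img, m))
  expect_equal(extract_features(img * 0, m),
               extract_features(matrix(0, 64, 64), m))
  expect_error(extract_features(matrix(0, 32, 32), m), "input side")
})

test_that("classification probabilities live on the simplex and respect permutations", {
  cfg <- micro_config(5)
  m <- build_model(cfg, seed = 7)
  set.seed(27)
  img <- matrix(runif(16 * 16), 16, 16)
  f <- extract_features(img, m)
  p <- sequence_and_classify(f, m)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # zero head weights: uniform probabilities
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]][] <- 0
  expect_equal(as.vector(sequence_and_classify(f, m0)), rep(1 / 5, 5),
               tolerance = 1e-12)

  # permuting the head rows permutes the output identically
  perm <- c(3, 1, 5, 2, 4)
  mp <- m
  mp$params[["head.W"]] <- m$params[["head.W"]][perm, ]
  mp$params[["head.b"]] <- m$params[["head.b"]][perm]
  expect_equal(sequence_and_classify(f, mp), p[perm, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("model construction is seed-deterministic with bounded tiny size", {
  cfg <- model_config("tiny", n_classes = 8)
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$n_params, 200000)

  set.seed(28)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(sequence_and_classify(extract_features(img, m1), m1),
                   sequence_and_classify(extract_features(img, m2), m2))

  # full-scale preset: B0-family depth, reported not trained
  paper <- build_model(model_config("paper", n_classes = 40), seed = 1)
  expect_gte(paper$n_layers, 60)
  expect_lte(paper$n_layers, 140)
  expect_gt(paper$n_params, 1e6)
})

test_that("analytic gradients agree with central differences through the full network", {
  cfg <- micro_config(3)
  cfg$blocks <- list(list(t = 2, c = 6, s = 2))
  m <- build_model(cfg, seed = 2)
  set.seed(29)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- c(1L, 3L)
  fw <- ppgid:::nn_forward(m, x, training = TRUE)
  gr <- ppgid:::nn_backward(m, ppgid:::softmax_ce(fw$logits, y)$dlogits, fw$caches)
  loss_at <- function(m) {
    f <- ppgid:::nn_forward(m, x, training = TRUE)
    ppgid:::softmax_ce(f$logits, y)$loss
  }
  eps <- 1e-5
  set.seed(30)
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) / max(1e-6, abs(num) + abs(gr[[nm]][i])),
                1e-4)
    }
  }
})
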