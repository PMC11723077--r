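#' Classifier configuration
#'
#' Describes the CNN-LSTM architecture: a strided convolutional stem, a
#' stack of inverted-residual blocks (pointwise expansion, depthwise 3x3,
#' squeeze-and-excitation, pointwise projection, with a skip connection
#' when stride is 1 and channel counts match), and an LSTM that consumes
#' the rows of the final feature map as its time steps, followed by a
#' dense softmax head.
#'
#' Two presets are provided. `"tiny"` (side 64, stem 8 channels, 3 blocks,
#' 32 LSTM units) is the desk-scale configuration used throughout the test
#' suite; `"paper"` follows the published B0-family block layout (side
#' 224, 21 blocks, 256 LSTM units) and is provided for structural
#' inspection at full scale.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param n_classes number of subjects to discriminate (>= 2).
#' @param input_side input raster side; overrides the preset default.
#' @param activation hidden activation: `"swish"` (default), `"relu"` or
#'   `"leaky_relu"`.
#' @param lstm_units LSTM hidden width; overrides the preset default.
#' @param bn_momentum momentum of the batch-normalization running
#'   statistics in (0, 1]; 1 freezes them at their initial values.
#' @return an object of class `ppgnet_config`.
#' @export
model_config <- function(preset = c("tiny", "paper"), n_classes = 40,
                         input_side = NULL, activation = c("swish", "relu", "leaky_relu"),
                         lstm_units = NULL, bn_momentum = 0.9) {
  preset <- match.arg(preset)
  activation <- match.arg(activation)
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  cfg <- if (preset == "tiny") {
    list(input_side = 64, stem_channels = 8,
         blocks = list(list(t = 1, c = 16, s = 2),
                       list(t = 2, c = 16, s = 2),
                       list(t = 2, c = 16, s = 1)),
         lstm_units = 32)
  } else {
    blocks <- c(
      rep(list(list(t = 1, c = 16, s = 1)), 1),
      list(list(t = 4, c = 32, s = 2)), rep(list(list(t = 4, c = 32, s = 1)), 1),
      list(list(t = 4, c = 48, s = 2)), rep(list(list(t = 4, c = 48, s = 1)), 1),
      list(list(t = 4, c = 96, s = 2)), rep(list(list(t = 4, c = 96, s = 1)), 2),
      rep(list(list(t = 6, c = 112, s = 1)), 5),
      list(list(t = 6, c = 192, s = 2)), rep(list(list(t = 6, c = 192, s = 1)), 7))
    list(input_side = 224, stem_channels = 32, blocks = blocks,
         lstm_units = 256)
  }
  if (!is.null(input_side)) cfg$input_side <- input_side
  if (!is.null(lstm_units)) cfg$lstm_units <- lstm_units
  structure(c(cfg,
              list(preset = preset, n_classes = as.integer(n_classes),
                   in_channels = 1L, se_ratio = 4, activation = activation,
                   bn_momentum = bn_momentum)),
            class = "ppgnet_config")
}

# Compile the per-layer channel/shape bookkeeping.
compile_arch <- function(config) {
  side <- config$input_side
  layers <- list()
  side <- ceiling(side / 2)                     # stem stride 2
  cin <- config$stem_channels
  for (i in seq_along(config$blocks)) {
    bl <- config$blocks[[i]]
    if (!bl$s %in% c(1, 2)) stopf("block strides must be 1 or 2")
    cexp <- cin * bl$t
    layers[[i]] <- list(name = sprintf("blk%d", i), cin = cin, cexp = cexp,
                        cout = bl$c, stride = bl$s,
                        se_red = max(1L, as.integer(round(cin / config$se_ratio))),
                        residual = bl$s == 1 && cin == bl$c)
    side <- ceiling(side / bl$s)
    cin <- bl$c
  }
  D <- side * cin
  list(blocks = layers, feat_side = side, feat_channels = cin,
       seq_len = side, seq_dim = D)
}

#' Build a classifier model
#'
#' Initializes all parameters deterministically under a seed (He-scaled
#' normal weights for convolutions, uniform fan-in scaled weights for the
#' LSTM and head, forget-gate bias +1) and reports the parameter count.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initialization draw.
#' @return an object of class `ppgnet_model`: list with `params` (flat
#'   named list of arrays), `state` (batch-norm running statistics),
#'   `config`, `arch`, `n_params` and `n_layers` (weighted layers:
#'   convolutional + recurrent + dense).
#' @export
build_model <- function(config, seed = 1) {
  if (!inherits(config, "ppgnet_config")) stopf("config must be a model_config()")
  arch <- compile_arch(config)
  params <- list(); state <- list()
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  add_bn <- function(name, C) {
    params[[paste0(name, ".bn.g")]] <<- rep(1, C)
    params[[paste0(name, ".bn.b")]] <<- rep(0, C)
    state[[paste0(name, ".bn.mean")]] <<- rep(0, C)
    state[[paste0(name, ".bn.var")]] <<- rep(1, C)
  }
  n_layers <- 0
  withr::with_seed(seed, {
    params[["stem.W"]] <- he(c(3, 3, config$in_channels, config$stem_channels),
                             9 * config$in_channels)
    add_bn("stem", config$stem_channels)
    n_layers <- n_layers + 1
    for (bl in arch$blocks) {
      nm <- bl$name
      if (bl$cexp != bl$cin) {
        params[[paste0(nm, ".exp.W")]] <- matrix(
          rnorm(bl$cin * bl$cexp, 0, sqrt(2 / bl$cin)), bl$cin, bl$cexp)
        add_bn(paste0(nm, ".exp"), bl$cexp)
        n_layers <- n_layers + 1
      }
      params[[paste0(nm, ".dw.W")]] <- he(c(3, 3, bl$cexp), 9)
      add_bn(paste0(nm, ".dw"), bl$cexp)
      n_layers <- n_layers + 1
      params[[paste0(nm, ".se.W1")]] <- matrix(
        rnorm(bl$se_red * bl$cexp, 0, sqrt(2 / bl$cexp)), bl$se_red, bl$cexp)
      params[[paste0(nm, ".se.b1")]] <- rep(0, bl$se_red)
      params[[paste0(nm, ".se.W2")]] <- matrix(
        rnorm(bl$cexp * bl$se_red, 0, sqrt(2 / bl$se_red)), bl$cexp, bl$se_red)
      params[[paste0(nm, ".se.b2")]] <- rep(0, bl$cexp)
      n_layers <- n_layers + 2
      params[[paste0(nm, ".proj.W")]] <- matrix(
        rnorm(bl$cexp * bl$cout, 0, sqrt(2 / bl$cexp)), bl$cexp, bl$cout)
      add_bn(paste0(nm, ".proj"), bl$cout)
      n_layers <- n_layers + 1
    }
    H <- config$lstm_units; D <- arch$seq_dim
    u <- function(nr, nc, fan) matrix(runif(nr * nc, -1, 1) * sqrt(1 / fan), nr, nc)
    params[["lstm.Wx"]] <- u(4 * H, D, D)
    params[["lstm.Wh"]] <- u(4 * H, H, H)
    b <- rep(0, 4 * H); b[H + seq_len(H)] <- 1    # forget-gate bias
    params[["lstm.b"]] <- b
    params[["head.W"]] <- u(config$n_classes, H, H)
    params[["head.b"]] <- rep(0, config$n_classes)
    n_layers <- n_layers + 2
  })
  structure(list(params = params, state = state, config = config, arch = arch,
                 n_params = sum(vapply(params, length, 0L)),
                 n_layers = n_layers, seed = as.integer(seed)),
            class = "ppgnet_model")
}

#' @export
print.ppgnet_model <- function(x, ...) {
  cat(sprintf("<ppgnet_model '%s'> %d blocks, %s parameters, %d weighted layers, input %dx%d\n",
              x$config$preset, length(x$arch$blocks),
              format(x$n_params, big.mark = ","), x$n_layers,
              x$config$input_side, x$config$input_side))
  invisible(x)
}

# ---- forward / backward through the block stack ---------------------------

mbconv_forward <- function(x, params, bl, state, activation, training,
                           momentum = 0.9) {
  nm <- bl$name
  cache <- list(residual = bl$residual, x_in = if (bl$residual) x else NULL,
                has_exp = bl$cexp != bl$cin)
  h <- x
  bnf <- function(h, tag) {
    r <- bn_forward(h, params[[paste0(tag, ".bn.g")]], params[[paste0(tag, ".bn.b")]],
                    state[[paste0(tag, ".bn.mean")]], state[[paste0(tag, ".bn.var")]],
                    training = training, momentum = momentum)
    state[[paste0(tag, ".bn.mean")]] <<- r$run_mean
    state[[paste0(tag, ".bn.var")]] <<- r$run_var
    r
  }
  if (cache$has_exp) {
    r <- conv1x1_forward(h, params[[paste0(nm, ".exp.W")]])
    cache$exp <- r$cache; h <- r$out
    r <- bnf(h, paste0(nm, ".exp")); cache$exp_bn <- r$cache; h <- r$out
    r <- act_forward(h, activation); cache$exp_act <- r$cache; h <- r$out
  }
  r <- depthwise_forward(h, params[[paste0(nm, ".dw.W")]], bl$stride)
  cache$dw <- r$cache; h <- r$out
  r <- bnf(h, paste0(nm, ".dw")); cache$dw_bn <- r$cache; h <- r$out
  r <- act_forward(h, activation); cache$dw_act <- r$cache; h <- r$out
  r <- se_forward(h, params[[paste0(nm, ".se.W1")]], params[[paste0(nm, ".se.b1")]],
                  params[[paste0(nm, ".se.W2")]], params[[paste0(nm, ".se.b2")]],
                  activation)
  cache$se <- r$cache; h <- r$out
  r <- conv1x1_forward(h, params[[paste0(nm, ".proj.W")]])
  cache$proj <- r$cache; h <- r$out
  r <- bnf(h, paste0(nm, ".proj")); cache$proj_bn <- r$cache; h <- r$out
  if (bl$residual) h <- h + x
  list(out = h, cache = cache, state = state)
}

mbconv_backward <- function(dout, params, bl, cache, activation, grads) {
  nm <- bl$name
  dh <- dout
  r <- bn_backward(dh, cache$proj_bn)
  grads[[paste0(nm, ".proj.bn.g")]] <- r$dgamma
  grads[[paste0(nm, ".proj.bn.b")]] <- r$dbeta
  dh <- r$dx
  r <- conv1x1_backward(dh, params[[paste0(nm, ".proj.W")]], cache$proj)
  grads[[paste0(nm, ".proj.W")]] <- r$dW
  dh <- r$dx
  r <- se_backward(dh, cache$se)
  grads[[paste0(nm, ".se.W1")]] <- r$dW1; grads[[paste0(nm, ".se.b1")]] <- r$db1
  grads[[paste0(nm, ".se.W2")]] <- r$dW2; grads[[paste0(nm, ".se.b2")]] <- r$db2
  dh <- r$dx
  dh <- act_backward(dh, cache$dw_act, activation)
  r <- bn_backward(dh, cache$dw_bn)
  grads[[paste0(nm, ".dw.bn.g")]] <- r$dgamma
  grads[[paste0(nm, ".dw.bn.b")]] <- r$dbeta
  dh <- r$dx
  r <- depthwise_backward(dh, params[[paste0(nm, ".dw.W")]], cache$dw)
  grads[[paste0(nm, ".dw.W")]] <- r$dW
  dh <- r$dx
  if (cache$has_exp) {
    dh <- act_backward(dh, cache$exp_act, activation)
    r <- bn_backward(dh, cache$exp_bn)
    grads[[paste0(nm, ".exp.bn.g")]] <- r$dgamma
    grads[[paste0(nm, ".exp.bn.b")]] <- r$dbeta
    dh <- r$dx
    r <- conv1x1_backward(dh, params[[paste0(nm, ".exp.W")]], cache$exp)
    grads[[paste0(nm, ".exp.W")]] <- r$dW
    dh <- r$dx
  }
  if (cache$residual) dh <- dh + dout
  list(dx = dh, grads = grads)
}

features_forward <- function(model, x, training = FALSE) {
  params <- model$params; state <- model$state
  activation <- model$config$activation
  momentum <- model$config$bn_momentum %||% 0.9
  caches <- list()
  r <- conv2d_forward(x, params[["stem.W"]], NULL, stride = 2)
  caches$stem <- r$cache; h <- r$out
  r <- bn_forward(h, params[["stem.bn.g"]], params[["stem.bn.b"]],
                  state[["stem.bn.mean"]], state[["stem.bn.var"]], training,
                  momentum = momentum)
  state[["stem.bn.mean"]] <- r$run_mean; state[["stem.bn.var"]] <- r$run_var
  caches$stem_bn <- r$cache; h <- r$out
  r <- act_forward(h, activation); caches$stem_act <- r$cache; h <- r$out
  caches$blocks <- vector("list", length(model$arch$blocks))
  for (i in seq_along(model$arch$blocks)) {
    r <- mbconv_forward(h, params, model$arch$blocks[[i]], state,
                        activation, training, momentum = momentum)
    caches$blocks[[i]] <- r$cache
    state <- r$state
    h <- r$out
  }
  list(out = h, caches = caches, state = state)
}

features_backward <- function(model, dfeat, caches) {
  params <- model$params
  activation <- model$config$activation
  grads <- list()
  dh <- dfeat
  for (i in rev(seq_along(model$arch$blocks))) {
    r <- mbconv_backward(dh, params, model$arch$blocks[[i]],
                         caches$blocks[[i]], activation, grads)
    grads <- r$grads
    dh <- r$dx
  }
  dh <- act_backward(dh, caches$stem_act, activation)
  r <- bn_backward(dh, caches$stem_bn)
  grads[["stem.bn.g"]] <- r$dgamma; grads[["stem.bn.b"]] <- r$dbeta
  dh <- r$dx
  r <- conv2d_backward(dh, params[["stem.W"]], caches$stem)
  grads[["stem.W"]] <- r$dW
  grads
}

# feature map (H', W', C', B) -> sequence (D, T, B): time steps are the
# rows of the final feature map, each step the concatenation of that row
# across columns and channels.
features_to_sequence <- function(feat) {
  d <- dim(feat)
  xs <- aperm(feat, c(2, 3, 1, 4))      # (W, C, H, B)
  dim(xs) <- c(d[2] * d[3], d[1], d[4]) # (D, T, B)
  xs
}

sequence_gradient_to_features <- function(dxs, d) {
  dim(dxs) <- c(d[2], d[3], d[1], d[4])
  aperm(dxs, c(3, 1, 2, 4))
}

classify_forward <- function(model, feat) {
  params <- model$params
  xs <- features_to_sequence(feat)
  r <- lstm_forward(xs, params[["lstm.Wx"]], params[["lstm.Wh"]], params[["lstm.b"]])
  lc <- r$cache
  r2 <- dense_forward(r$out, params[["head.W"]], params[["head.b"]])
  list(logits = r2$out, probs = softmax_cols(r2$out),
       caches = list(lstm = lc, head = r2$cache, feat_dim = dim(feat)))
}

classify_backward <- function(model, dlogits, caches, grads) {
  params <- model$params
  r <- dense_backward(dlogits, params[["head.W"]], caches$head)
  grads[["head.W"]] <- r$dW; grads[["head.b"]] <- r$db
  r2 <- lstm_backward(r$dx, caches$lstm)
  grads[["lstm.Wx"]] <- r2$dWx; grads[["lstm.Wh"]] <- r2$dWh
  grads[["lstm.b"]] <- r2$db
  list(dfeat = sequence_gradient_to_features(r2$dxs, caches$feat_dim),
       grads = grads)
}

nn_forward <- function(model, x, training = FALSE) {
  f <- features_forward(model, x, training)
  cfw <- classify_forward(model, f$out)
  list(probs = cfw$probs, logits = cfw$logits,
       caches = list(features = f$caches, classify = cfw$caches),
       state = f$state)
}

nn_backward <- function(model, dlogits, caches) {
  r <- classify_backward(model, dlogits, caches$classify, list())
  features_backward_grads <- features_backward(model, r$dfeat, caches$features)
  c(r$grads, features_backward_grads)
}

# ---- exported functional surface ------------------------------------------

#' Inverted-residual (MBConv) block
#'
#' Pointwise expansion, depthwise 3x3 convolution, squeeze-and-excitation,
#' pointwise projection (batch normalization after each convolution,
#' activation after expansion and depthwise stages); the input is added
#' back when the stride is 1 and input/output channel counts match.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, B)`.
#' @param params named list of block weights as produced by
#'   [build_model()] for one block, with the `blkN.` prefix stripped
#'   (`exp.W`, `dw.W`, `se.W1`, ..., `proj.W`, and `*.bn.g` / `*.bn.b`).
#' @param stride 1 or 2.
#' @param activation hidden activation name.
#' @return the block output feature map.
#' @export
mbconv <- function(x, params, stride = 1, activation = "swish") {
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x), 1)
  cin <- dim(x)[3]
  cexp <- if (!is.null(params[["exp.W"]])) ncol(params[["exp.W"]]) else cin
  cout <- ncol(params[["proj.W"]])
  if (nrow(params[["proj.W"]]) != cexp)
    stopf("incompatible block weights: projection expects %d channels, have %d",
          nrow(params[["proj.W"]]), cexp)
  bl <- list(name = "blk", cin = cin, cexp = cexp, cout = cout,
             stride = stride, se_red = nrow(params[["se.W1"]]),
             residual = stride == 1 && cin == cout)
  p2 <- params
  names(p2) <- paste0("blk.", names(params))
  state <- list()
  for (tag in c("exp", "dw", "proj")) {
    key <- paste0("blk.", tag, ".bn.")
    if (!is.null(p2[[paste0(key, "g")]])) {
      C <- length(p2[[paste0(key, "g")]])
      state[[paste0(key, "mean")]] <- rep(0, C)
      state[[paste0(key, "var")]] <- rep(1, C)
    }
  }
  out <- mbconv_forward(x, p2, bl, state, activation, training = TRUE)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Run the convolutional feature extractor
#'
#' Stem convolution followed by the inverted-residual block stack.
#'
#' @param image a `side x side` raster, `(side, side, 1)` array, or a batch
#'   `(side, side, 1, B)`; side must equal `config$input_side`.
#' @param model a `ppgnet_model` (or fitted [ppgnet]).
#' @param training use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`) in batch normalization.
#' @return final feature map `(H', W', C', B)`.
#' @export
extract_features <- function(image, model, training = FALSE) {
  x <- as_input_batch(image, model$config$input_side)
  features_forward(model, x, training)$out
}

#' Sequence the feature map and classify
#'
#' Reshapes the final feature map into a sequence of row vectors (one time
#' step per feature-map row), runs the LSTM, and maps the final hidden
#' state through the dense softmax head.
#'
#' @param features feature map `(H', W', C')` or `(H', W', C', B)`.
#' @param model a `ppgnet_model` (or fitted [ppgnet]).
#' @return matrix of class probabilities `(n_classes, B)`; columns sum
#'   to 1.
#' @export
sequence_and_classify <- function(features, model) {
  if (length(dim(features)) == 3) dim(features) <- c(dim(features), 1)
  classify_forward(model, features)$probs
}

as_input_batch <- function(image, side) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1, 1))
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1)
  if (dim(image)[1] != side || dim(image)[2] != side)
    stopf("input side %dx%d does not match the model input side %d",
          dim(image)[1], dim(image)[2], side)
  image
}
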