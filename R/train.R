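#' Hyperparameter settings for the ablation grid
#'
#' The three preset training settings varied in the ablation: batch size,
#' hidden activation, optimizer and learning rate. Setting 1 pairs batch
#' 16 with SGD at 0.01 and the default Swish hidden activation; setting 2
#' pairs batch 32 with Adam at 0.001 and ReLU; setting 3 pairs batch 64
#' with RMSprop at 0.0001 and leaky ReLU.
#'
#' @param setting_id 1, 2 or 3.
#' @return an object of class `train_setting` with fields `setting_id`,
#'   `batch_size`, `hidden_activation`, `optimizer`, `learning_rate`.
#' @export
train_setting <- function(setting_id = 2) {
  if (!setting_id %in% 1:3) stopf("setting_id must be 1, 2 or 3")
  row <- list(
    list(batch_size = 16, hidden_activation = "swish",
         optimizer = "sgd", learning_rate = 0.01),
    list(batch_size = 32, hidden_activation = "relu",
         optimizer = "adam", learning_rate = 0.001),
    list(batch_size = 64, hidden_activation = "leaky_relu",
         optimizer = "rmsprop", learning_rate = 0.0001))[[setting_id]]
  structure(c(list(setting_id = as.integer(setting_id)), row),
            class = "train_setting")
}

#' @export
print.train_setting <- function(x, ...) {
  cat(sprintf("<train_setting %d> batch %d, %s activation, %s @ lr %g\n",
              x$setting_id, x$batch_size, x$hidden_activation,
              x$optimizer, x$learning_rate))
  invisible(x)
}

make_optimizer <- function(kind, lr) {
  state <- new.env(parent = emptyenv())
  state$t <- 0
  step <- switch(kind,
    sgd = function(params, grads) {
      for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
      params
    },
    adam = function(params, grads) {
      state$t <- state$t + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(grads)) {
        if (is.null(state[[paste0("m.", nm)]])) {
          state[[paste0("m.", nm)]] <- grads[[nm]] * 0
          state[[paste0("v.", nm)]] <- grads[[nm]] * 0
        }
        m <- b1 * state[[paste0("m.", nm)]] + (1 - b1) * grads[[nm]]
        v <- b2 * state[[paste0("v.", nm)]] + (1 - b2) * grads[[nm]]^2
        state[[paste0("m.", nm)]] <- m
        state[[paste0("v.", nm)]] <- v
        mhat <- m / (1 - b1^state$t)
        vhat <- v / (1 - b2^state$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      params
    },
    rmsprop = function(params, grads) {
      rho <- 0.9; eps <- 1e-8
      for (nm in names(grads)) {
        if (is.null(state[[paste0("v.", nm)]]))
          state[[paste0("v.", nm)]] <- grads[[nm]] * 0
        v <- rho * state[[paste0("v.", nm)]] + (1 - rho) * grads[[nm]]^2
        state[[paste0("v.", nm)]] <- v
        params[[nm]] <- params[[nm]] - lr * grads[[nm]] / sqrt(v + eps)
      }
      params
    },
    stopf("unknown optimizer '%s'", kind))
  step
}

resolve_xy <- function(x, labels, classes = NULL) {
  if (inherits(x, "gram_dataset")) {
    labels <- x$labels
    x <- as_image_array(x)
  }
  if (is.null(labels)) stopf("labels are required when x is a plain array")
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stopf("labels contain classes unknown to the model")
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  list(x = x, y = y, classes = classes)
}

eval_loss_acc <- function(model, x, y, batch_size = 64) {
  n <- dim(x)[3]
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- array(x[, , idx], c(dim(x)[1], dim(x)[2], 1, length(idx)))
    fw <- nn_forward(model, xb, training = FALSE)
    sc <- softmax_ce(fw$logits, y[idx])
    loss <- loss + sc$loss * length(idx)
    correct <- correct + sum(apply(fw$probs, 2, which.max) == y[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Fit the PPG Gram-image classifier
#'
#' Trains the CNN-LSTM classifier on a labelled set of Gram-image rasters
#' by minibatch backpropagation on the categorical cross-entropy.
#' A validation fraction is carved from the training data (after any
#' augmentation) to drive early stopping: training halts when the
#' validation loss has not improved for `patience` consecutive epochs, and
#' the weights of the best validation epoch are restored.
#'
#' @param x a `gram_dataset`, or a `(side, side, n)` array of rasters.
#' @param labels subject labels (taken from `x` when it is a
#'   `gram_dataset`).
#' @param config a [model_config()]; its activation is overridden by the
#'   setting's hidden activation.
#' @param setting a [train_setting()].
#' @param epochs maximum number of epochs (default 25).
#' @param patience early-stopping patience in epochs (default 10).
#' @param val_frac validation fraction carved from the training data.
#' @param seed integer seed controlling initialization, the validation
#'   carve and minibatch shuffling.
#' @param verbose print per-epoch progress.
#' @return an object of class `ppgnet`: the fitted model (params, state,
#'   config, arch), `classes`, `history` (per-epoch train/validation loss
#'   and accuracy), `best_epoch`, `stopped_epoch` and the `setting` used.
#' @seealso [predict.ppgnet()], [evaluate()]
#' @export
ppgnet <- function(x, labels = NULL, config = NULL,
                   setting = train_setting(2), epochs = 25, patience = 10,
                   val_frac = 0.1, seed = 1, verbose = FALSE) {
  d <- resolve_xy(x, labels)
  n <- dim(d$x)[3]
  if (n == 0) stopf("empty training data")
  if (is.null(config))
    config <- model_config("tiny", n_classes = length(d$classes),
                           input_side = dim(d$x)[1])
  if (config$n_classes != length(d$classes))
    stopf("config expects %d classes but the data has %d",
          config$n_classes, length(d$classes))
  config$activation <- setting$hidden_activation
  model <- build_model(config, seed = seed)
  opt <- make_optimizer(setting$optimizer, setting$learning_rate)

  withr::with_seed(child_seed(seed, 1), {
    n_val <- max(if (val_frac > 0) 1 else 0, round(val_frac * n))
    val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) stopf("no training records left after the validation carve")
  xv <- d$x[, , val_idx, drop = FALSE]; yv <- d$y[val_idx]
  xt <- d$x[, , tr_idx, drop = FALSE]; yt <- d$y[tr_idx]

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0)
  wait <- 0; stopped <- epochs
  for (epoch in seq_len(epochs)) {
    order_idx <- withr::with_seed(child_seed(seed, 100 + epoch),
                                  sample(length(yt)))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, length(order_idx), by = setting$batch_size)) {
      idx <- order_idx[start:min(start + setting$batch_size - 1, length(order_idx))]
      xb <- array(xt[, , idx], c(dim(xt)[1], dim(xt)[2], 1, length(idx)))
      fw <- nn_forward(model, xb, training = TRUE)
      model$state <- fw$state
      sc <- softmax_ce(fw$logits, yt[idx])
      grads <- nn_backward(model, sc$dlogits, fw$caches)
      model$params <- opt(model$params, grads)
      ep_loss <- ep_loss + sc$loss * length(idx)
      ep_correct <- ep_correct + sum(apply(fw$probs, 2, which.max) == yt[idx])
    }
    tr <- c(loss = ep_loss / length(yt), acc = ep_correct / length(yt))
    va <- if (length(val_idx) > 0) eval_loss_acc(model, xv, yv) else c(loss = NA, acc = NA)
    history[epoch, ] <- list(epoch, tr[["loss"]], tr[["acc"]],
                             va[["loss"]], va[["acc"]])
    if (verbose)
      message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tr[["loss"]], tr[["acc"]],
                      va[["loss"]], va[["acc"]]))
    monitor <- if (length(val_idx) > 0) va[["loss"]] else tr[["loss"]]
    if (monitor < best$loss) {
      best <- list(loss = monitor, params = model$params,
                   state = model$state, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(params = model$params, state = model$state,
                 config = model$config, arch = model$arch,
                 n_params = model$n_params, n_layers = model$n_layers,
                 classes = d$classes, history = history,
                 best_epoch = best$epoch, stopped_epoch = stopped,
                 setting = setting, seed = as.integer(seed)),
            class = c("ppgnet", "ppgnet_model"))
}

#' Predict subject identities for Gram-image rasters
#'
#' @param object a fitted [ppgnet].
#' @param newdata a `gram_dataset`, a single `side x side` matrix, or a
#'   `(side, side, n)` array.
#' @param type `"class"` for predicted labels, `"prob"` for the class
#'   probability matrix (n x n_classes).
#' @param ... unused.
#' @export
predict.ppgnet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gram_dataset")) newdata <- as_image_array(newdata)
  if (is.matrix(newdata)) dim(newdata) <- c(dim(newdata), 1)
  side <- object$config$input_side
  n <- dim(newdata)[3]
  probs <- matrix(NA_real_, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    xb <- array(newdata[, , idx], c(side, side, 1, length(idx)))
    fw <- nn_forward(object, xb, training = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  if (type == "prob") probs
  else factor(object$classes[max.col(probs)], levels = object$classes)
}

#' @export
print.ppgnet <- function(x, ...) {
  cat(sprintf("<ppgnet> %d classes, %s parameters; trained %d epoch(s), best epoch %d\n",
              length(x$classes), format(x$n_params, big.mark = ","),
              x$stopped_epoch, x$best_epoch))
  invisible(x)
}

#' @export
summary.ppgnet <- function(object, ...) {
  h <- object$history
  cat(sprintf("Gram-image CNN-LSTM classifier ('%s' preset)\n", object$config$preset))
  cat(sprintf("  classes: %d (%s%s)\n", length(object$classes),
              paste(head(object$classes, 5), collapse = ", "),
              if (length(object$classes) > 5) ", ..." else ""))
  cat(sprintf("  parameters: %s in %d weighted layers\n",
              format(object$n_params, big.mark = ","), object$n_layers))
  print(object$setting)
  cat(sprintf("  epochs run: %d (best validation epoch %d)\n",
              object$stopped_epoch, object$best_epoch))
  if (nrow(h) > 0)
    cat(sprintf("  final: train acc %.3f, val acc %.3f\n",
                h$train_acc[nrow(h)], h$val_acc[nrow(h)]))
  invisible(object)
}

#' @export
coef.ppgnet <- function(object, ...) object$params

#' Plot the training history
#'
#' @param x a fitted [ppgnet].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ppgnet <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", ...)
  invisible(x)
}

#' Export the training history as CSV
#'
#' Writes the per-epoch train/validation loss and accuracy together with
#' the run provenance (run id, seed, setting, preset) as leading columns.
#'
#' @param object a fitted [ppgnet].
#' @param path CSV path.
#' @export
write_training_history <- function(object, path) {
  h <- object$history
  run_id <- sprintf("%s-set%d-seed%d", object$config$preset,
                    object$setting$setting_id, object$seed)
  out <- cbind(data.frame(run_id = run_id, seed = object$seed,
                          setting_id = object$setting$setting_id,
                          preset = object$config$preset), h)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model as plain text
#'
#' Serializes the parameters, running statistics, configuration and class
#' labels to an RDS-free, text-only format (dput) so checkpoints survive
#' text-only pipelines.
#'
#' @param object a fitted `ppgnet` or `ppgnet_model`.
#' @param path file path.
#' @export
save_ppgnet <- function(object, path) {
  obj <- unclass(object)
  obj$arch <- NULL     # recompiled on load
  dput(obj, file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(path)
}

#' @rdname save_ppgnet
#' @export
load_ppgnet <- function(path) {
  obj <- dget(path)
  obj$config <- structure(obj$config, class = "ppgnet_config")
  obj$arch <- compile_arch(obj$config)
  if (!is.null(obj$setting))
    obj$setting <- structure(obj$setting, class = "train_setting")
  cls <- if (!is.null(obj$classes)) c("ppgnet", "ppgnet_model") else "ppgnet_model"
  structure(obj, class = cls)
}
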