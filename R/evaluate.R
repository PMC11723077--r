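#' Evaluate a fitted classifier on labelled test data
#'
#' Argmax predictions are tallied into a confusion matrix (rows = true
#' class, columns = predicted class) from which per-class precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1 (their harmonic mean,
#' defined as 0 when the denominator is 0) are derived, together with
#' macro (unweighted) and weighted (support-weighted) averages and overall
#' accuracy.
#'
#' @param model a fitted [ppgnet].
#' @param test a `gram_dataset`, or a `(side, side, n)` array with
#'   `labels`.
#' @param labels test labels when `test` is a plain array.
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(model, test, labels = NULL) {
  d <- resolve_xy(test, labels, classes = model$classes)
  if (length(d$y) == 0) stopf("empty test set")
  pred <- predict(model, d$x, type = "class")
  truth <- factor(model$classes[d$y], levels = model$classes)
  eval_report(table(truth = truth, predicted = pred))
}

#' Build an evaluation report from a confusion matrix
#'
#' @param confusion square matrix of counts, rows = truth, columns =
#'   predicted, identically ordered.
#' @return an object of class `eval_report`: the confusion matrix, a
#'   per-class data frame (`class`, `precision`, `recall`, `f1`,
#'   `support`), `macro` and `weighted` averages, and `accuracy`.
#' @export
eval_report <- function(confusion) {
  confusion <- as.matrix(unclass(confusion))
  if (nrow(confusion) != ncol(confusion))
    stopf("confusion matrix must be square")
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, predicted)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (any(support == 0) || any(predicted == 0))
    warning("classes with zero support or zero predictions score 0 by convention")
  per_class <- data.frame(class = rownames(confusion) %||% as.character(seq_along(tp)),
                          precision = precision, recall = recall, f1 = f1,
                          support = support, row.names = NULL)
  wavg <- function(v) sum(v * support) / sum(support)
  structure(list(confusion = confusion,
                 per_class = per_class,
                 macro = c(precision = mean(precision), recall = mean(recall),
                           f1 = mean(f1)),
                 weighted = c(precision = wavg(precision), recall = wavg(recall),
                              f1 = wavg(f1)),
                 accuracy = sum(tp) / sum(confusion)),
            class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classes, %d records, accuracy %.3f\n",
              nrow(x$confusion), sum(x$confusion), x$accuracy))
  cat(sprintf("  macro    P %.3f R %.3f F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("  weighted P %.3f R %.3f F1 %.3f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Export an evaluation report as CSV
#'
#' Writes the per-class rows followed by macro/weighted footer rows, and
#' optionally the confusion matrix.
#'
#' @param report an `eval_report`.
#' @param path CSV path for the classification report.
#' @param confusion_path optional CSV path for the confusion matrix.
#' @export
write_eval_report <- function(report, path, confusion_path = NULL) {
  pc <- report$per_class
  footer <- data.frame(class = c("macro_avg", "weighted_avg"),
                       precision = c(report$macro["precision"], report$weighted["precision"]),
                       recall = c(report$macro["recall"], report$weighted["recall"]),
                       f1 = c(report$macro["f1"], report$weighted["f1"]),
                       support = c(sum(pc$support), sum(pc$support)))
  write.csv(rbind(pc, footer), path, row.names = FALSE)
  if (!is.null(confusion_path))
    write.csv(as.data.frame(report$confusion), confusion_path, row.names = FALSE)
  invisible(path)
}

#' Hyperparameter x dataset-variant ablation harness
#'
#' Trains and evaluates one model per (setting, variant) cell at the
#' configured scale and returns a tidy accuracy table.
#'
#' @param dataset a raw-provenance `ppg_dataset`.
#' @param settings list of [train_setting()] objects.
#' @param variants character vector drawn from `"raw"`, `"filtered"`,
#'   `"mixed"`.
#' @param side raster side for the Gram images.
#' @param config optional [model_config()] shared by all cells.
#' @param train_frac,epochs,patience,seed training protocol knobs.
#' @param plan optional [augmentation_plan()] applied to each training
#'   split (`NULL` to skip augmentation).
#' @return data frame with one row per cell: `setting_id`, `variant`,
#'   `accuracy`, `macro_f1`, `weighted_f1`, `n_train`, `n_test`.
#' @export
ablation <- function(dataset, settings = list(train_setting(2)),
                     variants = "mixed", side = 64, config = NULL,
                     train_frac = 0.8, epochs = 25, patience = 10,
                     seed = 1, plan = NULL) {
  if (length(settings) < 1 || length(variants) < 1)
    stopf("need at least one setting and one variant")
  rows <- list()
  for (variant in variants) {
    gd <- dataset_to_grams(dataset, variant, side = side)
    sp <- split_dataset(gd, train_frac = train_frac, seed = seed)
    train <- if (is.null(plan)) sp$train else augment_dataset(sp$train, plan)
    for (st in settings) {
      fit <- ppgnet(train, config = config, setting = st, epochs = epochs,
                    patience = patience, seed = seed)
      rep <- evaluate(fit, sp$test)
      rows[[length(rows) + 1]] <- data.frame(
        setting_id = st$setting_id, variant = variant,
        accuracy = rep$accuracy,
        macro_f1 = unname(rep$macro["f1"]),
        weighted_f1 = unname(rep$weighted["f1"]),
        n_train = length(sp$train), n_test = length(sp$test))
    }
  }
  do.call(rbind, rows)
}
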