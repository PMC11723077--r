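#' Labelled Gram-image dataset
#'
#' Container for classifier inputs: a list of equal-sized rasters with
#' subject labels, split tags and per-record provenance.
#'
#' @param images list of `side x side` matrices in \[0, 1\].
#' @param labels character vector of subject labels, one per image.
#' @param meta optional data frame with one row per image; columns
#'   `record_id`, `source_id`, `subject_id`, `provenance`, `split`,
#'   `op_chain` are filled with defaults when missing.
#' @return an object of class `gram_dataset`.
#' @export
gram_dataset <- function(images, labels, meta = NULL) {
  if (length(images) != length(labels))
    stopf("images and labels must have the same length")
  if (is.null(meta)) {
    meta <- data.frame(record_id = sprintf("G%05d", seq_along(images)),
                       source_id = sprintf("G%05d", seq_along(images)),
                       subject_id = as.character(labels),
                       provenance = "original", split = NA_character_,
                       op_chain = "", stringsAsFactors = FALSE)
  }
  structure(list(images = images, labels = as.character(labels), meta = meta),
            class = "gram_dataset")
}

#' @export
length.gram_dataset <- function(x) length(x$images)

#' @export
print.gram_dataset <- function(x, ...) {
  side <- nrow(x$images[[1]])
  cat(sprintf("<gram_dataset> %d images (%dx%d), %d subjects; splits: %s\n",
              length(x$images), side, side, length(unique(x$labels)),
              paste(names(table(x$meta$split, useNA = "ifany")), collapse = "/")))
  invisible(x)
}

subset_gram_dataset <- function(gd, idx) {
  structure(list(images = gd$images[idx], labels = gd$labels[idx],
                 meta = gd$meta[idx, , drop = FALSE]),
            class = "gram_dataset")
}

#' Convert a signal dataset to rendered Gram images
#'
#' Runs each recording through the preprocessing pipeline for the chosen
#' variant ([make_variant_dataset()]), converts it to its Gram matrix and
#' renders it at a fixed side, producing the classifier-ready dataset.
#'
#' @param dataset a raw-provenance `ppg_dataset`.
#' @param variant `"raw"`, `"filtered"` or `"mixed"` (mixed doubles the
#'   record count).
#' @param side raster side in pixels.
#' @param params a [savgol_params].
#' @return a [gram_dataset()].
#' @export
dataset_to_grams <- function(dataset, variant = c("raw", "filtered", "mixed"),
                             side = 64, params = savgol_params()) {
  variant <- match.arg(variant)
  vd <- make_variant_dataset(dataset, variant, params)
  images <- lapply(vd$signals, function(s) render_gram(signal_gram(s), side = side))
  gram_dataset(images, vd$manifest$subject_id,
               meta = data.frame(record_id = vd$manifest$signal_id,
                                 source_id = vd$manifest$signal_id,
                                 subject_id = vd$manifest$subject_id,
                                 provenance = vd$manifest$provenance,
                                 split = vd$manifest$split,
                                 op_chain = "", stringsAsFactors = FALSE))
}

#' Stack a gram_dataset into an array
#'
#' @param gd a `gram_dataset`.
#' @return `side x side x n` numeric array.
#' @export
as_image_array <- function(gd) {
  side <- nrow(gd$images[[1]])
  array(unlist(gd$images, use.names = FALSE), c(side, side, length(gd$images)))
}

#' Stratified train/test split
#'
#' Splits per subject so every class appears in both subsets: for each
#' subject, `round(train_frac * n)` records go to the training set and the
#' rest to the test set, with a seeded shuffle. The two parts are disjoint
#' and together contain every record.
#'
#' @param data a `gram_dataset` or `ppg_dataset`.
#' @param train_frac training fraction in (0, 1); default 0.8 (the 80/20
#'   convention for small datasets).
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `test`, each of the input class
#'   with `split` tags set.
#' @export
split_dataset <- function(data, train_frac = 0.8, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must lie in (0, 1)")
  labels <- if (inherits(data, "gram_dataset")) data$labels else data$manifest$subject_id
  n <- length(labels)
  split <- character(n)
  withr::with_seed(seed, {
    for (sid in unique(labels)) {
      idx <- which(labels == sid)
      if (length(idx) < 2)
        stopf("subject %s has %d record(s); need at least 2 to split", sid, length(idx))
      idx <- sample(idx)
      n_train <- round(train_frac * length(idx))
      n_train <- min(max(n_train, 1), length(idx) - 1)   # both sides non-empty
      split[idx[seq_len(n_train)]] <- "train"
      split[idx[-seq_len(n_train)]] <- "test"
    }
  })
  take <- function(tag) {
    idx <- which(split == tag)
    if (inherits(data, "gram_dataset")) {
      out <- subset_gram_dataset(data, idx)
      out$meta$split <- tag
      out
    } else {
      out <- data
      out$signals <- data$signals[idx]
      out$manifest <- data$manifest[idx, , drop = FALSE]
      out$manifest$split <- tag
      out
    }
  }
  list(train = take("train"), test = take("test"))
}
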