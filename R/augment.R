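#' Augmentation plan
#'
#' Training-set-only augmentation settings. The default per-copy operator
#' is drawn between (a) horizontal flip followed by singular-value
#' perturbation and (b) a random rotation bounded by `rotation_max`
#' degrees; labels are always inherited from the source image.
#'
#' @param flip_enabled enable the flip + SV-perturbation chain.
#' @param sv_sigma relative scale of the singular-value perturbation
#'   (each singular value is multiplied by `1 + N(0, sv_sigma)`).
#' @param pca_components number of principal components perturbed by
#'   [pca_perturb()], or `"all"`.
#' @param rotation_max rotation bound in degrees, at most 90; 0 disables
#'   rotation.
#' @param copies_per_image augmented copies generated per source image.
#' @param seed integer seed; augmentation is deterministic under it.
#' @return an object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(flip_enabled = TRUE, sv_sigma = 0.05,
                              pca_components = "all", rotation_max = 90,
                              copies_per_image = 10, seed = 1) {
  if (rotation_max < 0 || rotation_max > 90)
    stopf("rotation_max must lie in [0, 90] degrees")
  if (sv_sigma < 0) stopf("sv_sigma must be >= 0")
  if (!is.numeric(copies_per_image) || copies_per_image < 0 ||
      copies_per_image != floor(copies_per_image))
    stopf("copies_per_image must be a non-negative integer")
  structure(list(flip_enabled = isTRUE(flip_enabled), sv_sigma = sv_sigma,
                 pca_components = pca_components, rotation_max = rotation_max,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Horizontal flip
#'
#' Reverses the column order of a raster; an involution.
#'
#' @param m numeric matrix.
#' @return the flipped matrix.
#' @export
hflip <- function(m) {
  m <- as.matrix(m)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Singular-value perturbation
#'
#' Computes the SVD `U diag(d) V'`, multiplies each singular value by
#' `1 + e_i` with `e_i ~ N(0, sigma)` (negative results clipped to 0) and
#' reconstructs. `sigma = 0` is an exact round-trip; a rank-1 input stays
#' rank at most 1. Consumes the caller's RNG stream.
#'
#' @param m numeric matrix.
#' @param sigma relative perturbation scale, `>= 0`.
#' @return list with the perturbed matrix `out` and the applied post-clip
#'   relative changes `eps` (one per singular value). Use `$out` in
#'   pipelines.
#' @export
sv_perturb <- function(m, sigma = 0.05) {
  if (sigma < 0) stopf("sigma must be >= 0")
  m <- as.matrix(m)
  sv <- svd(m)
  d_new <- pmax(sv$d * (1 + rnorm(length(sv$d), 0, sigma)), 0)
  eps <- ifelse(sv$d > 0, d_new / sv$d - 1, 0)
  list(out = sv$u %*% (d_new * t(sv$v)), eps = eps)
}

#' Principal-component perturbation
#'
#' Centers the rows (observations) on the column means, projects onto the
#' principal components of the row space, scales the scores of the top `k`
#' components by `1 + N(0, sigma)`, and reconstructs with the
#' discarded-component residual re-added, so `sigma = 0` reproduces the
#' input exactly for any `k`. Consumes the caller's RNG stream.
#'
#' @param m numeric matrix (square raster).
#' @param k number of leading components to perturb, `1 <= k <= ncol(m)`,
#'   or `"all"`.
#' @param sigma relative perturbation scale.
#' @return the perturbed matrix.
#' @export
pca_perturb <- function(m, k = "all", sigma = 0.05) {
  m <- as.matrix(m)
  if (identical(k, "all")) k <- ncol(m)
  if (!is_count(k) || k > ncol(m)) stopf("k must be an integer in [1, %d]", ncol(m))
  mu <- colMeans(m)
  Xc <- sweep(m, 2, mu)
  sv <- svd(Xc)
  scores <- sv$u %*% diag(sv$d, length(sv$d))   # rows projected on components
  kk <- min(k, length(sv$d))
  scale <- 1 + rnorm(kk, 0, sigma)
  scores[, seq_len(kk)] <- sweep(scores[, seq_len(kk), drop = FALSE], 2, scale, `*`)
  sweep(scores %*% t(sv$v), 2, mu, `+`)
}

#' Bounded rotation of a raster
#'
#' Rotates about the image centre, keeping dimensions; right angles
#' (multiples of 90) are exact index permutations, other angles use
#' bilinear interpolation with out-of-frame pixels filled with 0 (zero
#' Gram intensity means "no similarity", so background is neutral).
#'
#' @param m numeric matrix.
#' @param angle degrees, `|angle| <= 90`; positive is clockwise.
#' @return the rotated matrix, same dimensions.
#' @export
rotate_raster <- function(m, angle) {
  if (abs(angle) > 90) stopf("|angle| must be <= 90 degrees")
  m <- as.matrix(m)
  if (angle %% 360 == 0) return(m)
  if (angle %% 90 == 0) {
    k <- (angle / 90) %% 4
    rot90cw <- function(x) t(x[, rev(seq_len(ncol(x))), drop = FALSE])
    for (i in seq_len(k)) m <- rot90cw(m)
    return(m)
  }
  out <- EBImage::rotate(m, angle, filter = "bilinear",
                         output.dim = dim(m), bg.col = 0)
  pmin(pmax(as.matrix(out), 0), max(m))
}

#' Expand a training set with augmented copies
#'
#' Applies the plan to every record of a train-split dataset: each source
#' image contributes `copies_per_image` augmented copies in addition to
#' itself, each copy tagged with its source record and operator chain.
#' Labels are inherited; the result is deterministic under the plan seed.
#' Augmentation of validation/test records is refused (leakage guard).
#'
#' @param train a `gram_dataset` whose records are all tagged
#'   `split == "train"`.
#' @param plan an [augmentation_plan()].
#' @return a `gram_dataset` of size `length(train) * (1 + copies_per_image)`.
#' @export
augment_dataset <- function(train, plan = augmentation_plan()) {
  if (!inherits(train, "gram_dataset")) stopf("train must be a gram_dataset")
  if (!all(train$meta$split %in% "train"))
    stopf("augmentation is restricted to the training split (leakage guard)")
  ops <- c(if (plan$flip_enabled) "flip_sv",
           if (plan$rotation_max > 0) "rotate")
  if (plan$copies_per_image == 0 || length(ops) == 0) return(train)
  images <- train$images
  labels <- train$labels
  meta <- train$meta
  new_images <- list(); new_meta <- list(); new_labels <- character(0)
  withr::with_seed(plan$seed, {
    for (i in seq_along(images)) {
      for (cp in seq_len(plan$copies_per_image)) {
        op <- if (length(ops) == 1) ops else sample(ops, 1)
        if (op == "flip_sv") {
          img <- sv_perturb(hflip(images[[i]]), plan$sv_sigma)$out
          chain <- sprintf("hflip|sv_perturb(sigma=%g)", plan$sv_sigma)
        } else {
          ang <- runif(1, -plan$rotation_max, plan$rotation_max)
          img <- rotate_raster(images[[i]], ang)
          chain <- sprintf("rotate(angle=%.2f)", ang)
        }
        new_images[[length(new_images) + 1]] <- img
        new_labels <- c(new_labels, labels[i])
        new_meta[[length(new_meta) + 1]] <- data.frame(
          record_id = sprintf("%s_aug%02d", meta$record_id[i], cp),
          source_id = meta$record_id[i],
          subject_id = labels[i],
          provenance = "augmented", split = "train",
          op_chain = chain, stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(images = c(images, new_images),
                 labels = c(labels, new_labels),
                 meta = rbind(meta, do.call(rbind, new_meta))),
            class = "gram_dataset")
}

#' Write the augmentation provenance sidecar
#'
#' @param gd an augmented `gram_dataset`.
#' @param path CSV path; columns `record_id`, `source_id`, `subject_id`,
#'   `provenance`, `op_chain`.
#' @export
write_augmentation_sidecar <- function(gd, path) {
  write.csv(gd$meta[, c("record_id", "source_id", "subject_id",
                        "provenance", "op_chain")],
            path, row.names = FALSE)
  invisible(path)
}
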