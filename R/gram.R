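#' Gram-matrix image of a single signal
#'
#' Converts a normalized 1-D signal of length N into its N x N Gramian,
#' the outer product `G[m, n] = s[m] * s[n]`. This is the per-signal
#' operational form of the pairwise-dot-product Gram matrix: restricted to
#' one signal's sample pairs it yields a symmetric, positive semidefinite,
#' rank-1 matrix whose bright regions mark jointly large samples — the 2-D
#' "image" the classifier consumes. For the literal cross-signal form see
#' [cross_gram()].
#'
#' @param sig a normalized [ppg_signal] or a numeric vector.
#' @return an object of class `gram_image`: list with the matrix `G`, the
#'   `source_id` and the `value_range`.
#' @export
signal_gram <- function(sig) {
  s <- if (inherits(sig, "ppg_signal")) sig$samples else as.numeric(sig)
  if (length(s) == 0) stopf("cannot build a Gram image from an empty signal")
  G <- tcrossprod(s)
  structure(list(G = G,
                 source_id = if (inherits(sig, "ppg_signal")) sig$subject_id else NA_character_,
                 value_range = range(G)),
            class = "gram_image")
}

#' @export
print.gram_image <- function(x, ...) {
  cat(sprintf("<gram_image> %d x %d, values in [%.4g, %.4g]\n",
              nrow(x$G), ncol(x$G), x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' Cross-signal Gram matrix
#'
#' The matrix of pairwise dot products between M equal-length signals:
#' entry (i, j) is `sum_k s_i[k] * s_j[k]`. Used for similarity analysis
#' across recordings.
#'
#' @param signals list of [ppg_signal] or numeric vectors of equal length.
#' @return symmetric M x M numeric matrix.
#' @export
cross_gram <- function(signals) {
  if (length(signals) < 1) stopf("need at least one signal")
  vecs <- lapply(signals, function(s)
    if (inherits(s, "ppg_signal")) s$samples else as.numeric(s))
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1) stopf("signals must have equal length")
  S <- do.call(rbind, vecs)
  tcrossprod(S)
}

#' Render a Gram image as a fixed-size raster
#'
#' Min-max rescales the matrix to \[0, 1\] intensity and bilinearly
#' resamples it to `side x side`. A constant matrix (degenerate rescale)
#' renders as all-zero intensity by convention. Rendering is invariant to
#' positive scaling of the input matrix.
#'
#' @param image a `gram_image` or a plain numeric matrix.
#' @param side output side in pixels (default 64, the desk-scale classifier
#'   input; raise towards 224 for larger models).
#' @param channels number of identical channels to replicate the intensity
#'   into (default 1).
#' @return a `side x side` matrix in \[0, 1\], or a
#'   `side x side x channels` array when `channels > 1`.
#' @export
render_gram <- function(image, side = 64, channels = 1) {
  G <- if (inherits(image, "gram_image")) image$G else as.matrix(image)
  if (!is_count(side)) stopf("side must be a positive integer")
  lo <- min(G); hi <- max(G)
  M <- if (hi > lo) (G - lo) / (hi - lo) else array(0, dim(G))
  if (side != nrow(M) || side != ncol(M))
    M <- EBImage::resize(M, w = side, h = side, filter = "bilinear")
  M <- pmin(pmax(M, 0), 1)
  if (channels > 1) array(rep(M, channels), c(side, side, channels)) else M
}

#' Export a rendered Gram raster as a PNG image
#'
#' @param raster a `side x side` matrix in \[0, 1\] (e.g. from
#'   [render_gram()]).
#' @param path output PNG path.
#' @export
write_gram_png <- function(raster, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG export")
  png::writePNG(pmin(pmax(as.matrix(raster), 0), 1), target = path)
  invisible(path)
}
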