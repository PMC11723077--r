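#' Savitzky-Golay filter parameters
#'
#' The filter smooths by sliding least-squares polynomial fits: within each
#' window of `window_length` evenly spaced samples a polynomial of degree
#' `poly_order` is fitted and evaluated at the window centre, which for
#' evenly spaced data reduces to a fixed convolution. Defaults (window 11,
#' order 3) are a common choice for pulse waveforms at tens of Hz.
#'
#' @param window_length odd window length in samples.
#' @param poly_order polynomial degree, `0 <= poly_order < window_length`.
#' @return an object of class `savgol_params`.
#' @export
savgol_params <- function(window_length = 11, poly_order = 3) {
  if (!is_count(window_length) || window_length %% 2 == 0)
    stopf("window_length must be a positive odd integer")
  if (!is.numeric(poly_order) || poly_order < 0 || poly_order != floor(poly_order) ||
      poly_order >= window_length)
    stopf("poly_order must be an integer in [0, window_length)")
  structure(list(window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order)),
            class = "savgol_params")
}

#' Savitzky-Golay smoothing of a PPG signal
#'
#' Interior samples equal the centred least-squares polynomial fit over the
#' surrounding window; at the edges the first/last window's polynomial is
#' evaluated at the edge offsets, so the output keeps the input length.
#' Polynomials of degree at most `poly_order` are reproduced exactly.
#'
#' @param sig a [ppg_signal] (or numeric vector).
#' @param params a [savgol_params].
#' @return the smoothed signal with provenance `"filtered"` (numeric vector
#'   in, numeric vector out).
#' @export
savgol_smooth <- function(sig, params = savgol_params()) {
  x <- if (inherits(sig, "ppg_signal")) sig$samples else as.numeric(sig)
  if (length(x) < params$window_length)
    stopf("signal length %d is shorter than the filter window %d",
          length(x), params$window_length)
  y <- signal::sgolayfilt(x, p = params$poly_order, n = params$window_length)
  if (!inherits(sig, "ppg_signal")) return(y)
  out <- sig
  out$samples <- y
  out$provenance <- "filtered"
  out
}

#' Min-max normalization to \[0, 1\]
#'
#' Rescales a signal affinely so that its minimum maps to 0 and its
#' maximum to 1: `x' = (x - min(x)) / (max(x) - min(x))`. A constant
#' signal has no information to rescale and raises a degenerate-input
#' error rather than silently returning zeros.
#'
#' @param sig a [ppg_signal] (or numeric vector).
#' @return the normalized signal with provenance `"normalized"`.
#' @export
minmax_normalize <- function(sig) {
  x <- if (inherits(sig, "ppg_signal")) sig$samples else as.numeric(sig)
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 1e-9 * max(1, abs(hi)))   # constant up to numerical noise
    stopf("degenerate input: constant signal cannot be min-max normalized")
  y <- (x - lo) / (hi - lo)
  if (!inherits(sig, "ppg_signal")) return(y)
  out <- sig
  out$samples <- y
  out$provenance <- "normalized"
  out
}

#' Preprocessing pipeline for one signal
#'
#' The `"filtered"` variant applies Savitzky-Golay smoothing and then
#' min-max normalization; the `"raw"` variant normalizes only. Filtering
#' precedes normalization so the \[0, 1\] range is guaranteed at the stage
#' boundary feeding the Gram-matrix conversion.
#'
#' @param sig a [ppg_signal].
#' @param variant `"filtered"` or `"raw"`.
#' @param params a [savgol_params] (filtered variant only).
#' @return a normalized [ppg_signal].
#' @export
preprocess_pipeline <- function(sig, variant = c("filtered", "raw"),
                                params = savgol_params()) {
  variant <- match.arg(variant)
  if (variant == "filtered") sig <- savgol_smooth(sig, params)
  minmax_normalize(sig)
}

#' Build a preprocessed dataset variant
#'
#' From a raw dataset builds the `"raw"` variant (normalized-only copies),
#' the `"filtered"` variant (smoothed then normalized), or the `"mixed"`
#' variant: the union of both, in which every source recording contributes
#' two provenance-tagged records (so the record count doubles).
#'
#' @param dataset a raw-provenance `ppg_dataset`.
#' @param variant `"raw"`, `"filtered"` or `"mixed"`.
#' @param params a [savgol_params].
#' @return a `ppg_dataset` of normalized signals; the manifest `provenance`
#'   column records which branch each record came through.
#' @export
make_variant_dataset <- function(dataset, variant = c("raw", "filtered", "mixed"),
                                 params = savgol_params()) {
  variant <- match.arg(variant)
  if (!all(dataset$manifest$provenance == "raw"))
    stopf("make_variant_dataset expects a raw-provenance dataset")
  branch <- function(kind) {
    sigs <- lapply(dataset$signals, preprocess_pipeline,
                   variant = if (kind == "filtered") "filtered" else "raw",
                   params = params)
    man <- dataset$manifest
    man$provenance <- kind
    man$signal_id <- paste0(man$signal_id, "_", kind)
    list(signals = sigs, manifest = man)
  }
  parts <- switch(variant,
                  raw = list(branch("raw")),
                  filtered = list(branch("filtered")),
                  mixed = list(branch("raw"), branch("filtered")))
  structure(list(signals = do.call(c, lapply(parts, `[[`, "signals")),
                 profiles = dataset$profiles,
                 manifest = do.call(rbind, lapply(parts, `[[`, "manifest")),
                 config = dataset$config),
            class = "ppg_dataset")
}
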