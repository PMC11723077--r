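#' Sample stream sources
#'
#' A `stream_source` replays integer ADC samples in place of a live
#' sensor: from an in-memory vector, a single-column CSV file, or a live
#' generator driven by a [subject_profile]. The source yields samples in
#' order and reports exhaustion.
#'
#' @param x integer sample vector (`stream_from_vector`), path to a CSV
#'   with a `count` column (`stream_from_file`), or a [subject_profile]
#'   (`stream_from_generator`).
#' @param sampling_rate sampling rate in Hz.
#' @param config a [generator_config] (generator source only; noise and
#'   ADC settings are taken from it).
#' @param seed seed for the generator source.
#' @return an object of class `stream_source` with fields `take(n)`
#'   (returns the next `n` samples or errors when exhausted), `pos()`,
#'   `sampling_rate` and `origin`.
#' @export
stream_from_vector <- function(x, sampling_rate = 50) {
  x <- as.numeric(x)
  env <- new.env(parent = emptyenv())
  env$pos <- 0
  structure(list(
    take = function(n) {
      if (env$pos + n > length(x))
        stopf("stream exhausted: %d sample(s) requested, %d left",
              n, length(x) - env$pos)
      out <- x[env$pos + seq_len(n)]
      env$pos <- env$pos + n
      out
    },
    pos = function() env$pos,
    sampling_rate = sampling_rate, origin = "file"),
    class = "stream_source")
}

#' @rdname stream_from_vector
#' @export
stream_from_file <- function(x, sampling_rate = 50) {
  counts <- read.csv(x)$count
  src <- stream_from_vector(counts, sampling_rate)
  src
}

#' @rdname stream_from_vector
#' @export
stream_from_generator <- function(x, config = generator_config(), seed = 1) {
  profile <- x
  hi <- 2^config$adc_bits - 1
  env <- new.env(parent = emptyenv())
  env$pos <- 0
  env$buffer <- numeric(0)
  env$beat <- 0
  next_beat <- function() {
    env$beat <- env$beat + 1
    withr::with_seed(child_seed(seed, env$beat), {
      period <- profile$heart_period +
        if (profile$jitter_sd > 0) rnorm(1, 0, profile$jitter_sd) else 0
      period <- max(period, 10 / config$sampling_rate)
      b <- synth_beat(profile, config$sampling_rate, period = period)
      counts <- profile$baseline_level + profile$pulse_amplitude * b
      if (config$noise_sd > 0)
        counts <- counts + rnorm(length(b), 0, config$noise_sd)
      round(pmin(pmax(counts, 0), hi))
    })
  }
  structure(list(
    take = function(n) {
      # the stream is beat-continuous: successive beats are appended with
      # no phase reset, as a live sensor would deliver them
      while (length(env$buffer) < n)
        env$buffer <- c(env$buffer, next_beat())
      out <- env$buffer[seq_len(n)]
      env$buffer <- env$buffer[-seq_len(n)]
      env$pos <- env$pos + n
      out
    },
    pos = function() env$pos,
    sampling_rate = config$sampling_rate, origin = "generator"),
    class = "stream_source")
}

#' Discard the stabilization period and capture one window
#'
#' Discards exactly `round(stabilization * sampling_rate)` samples (the
#' settling period after a sensor is applied) and then captures `window`
#' samples as one recording.
#'
#' @param source a `stream_source`.
#' @param stabilization stabilization period in seconds (default 25).
#' @param window capture length in samples (default 300).
#' @param subject_id label attached to the captured signal.
#' @param adc_bits ADC resolution of the stream.
#' @return a raw-provenance [ppg_signal] of length `window`.
#' @export
stabilize_and_capture <- function(source, stabilization = 25, window = 300,
                                  subject_id = NA_character_, adc_bits = 18) {
  discard <- round(stabilization * source$sampling_rate)
  if (discard > 0) invisible(source$take(discard))
  ppg_signal(source$take(window), sampling_rate = source$sampling_rate,
             subject_id = subject_id, adc_bits = adc_bits, provenance = "raw")
}

#' Identify the subject of one captured window
#'
#' Runs the full chain on a single window: preprocessing (smoothing for
#' the `"filtered"` variant, then min-max normalization), Gram-matrix
#' conversion, rendering at the model's input side, and a forward pass.
#' The same code path as the offline pipeline, so offline and streaming
#' predictions agree exactly on the same window.
#'
#' @param window a [ppg_signal] (e.g. from [stabilize_and_capture()]).
#' @param model a fitted [ppgnet].
#' @param variant `"filtered"` or `"raw"` preprocessing variant.
#' @param params a [savgol_params].
#' @return an object of class `identification_result`: `label`, `probs`
#'   (named probability vector), `window_samples`, and `timings` (seconds
#'   per stage).
#' @export
identify <- function(window, model, variant = c("filtered", "raw"),
                     params = savgol_params()) {
  variant <- match.arg(variant)
  tm <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, sec = proc.time()[["elapsed"]] - t0)
  }
  pre <- tm(preprocess_pipeline(window, variant, params))
  gram <- tm(signal_gram(pre$val))
  rast <- tm(render_gram(gram$val, side = model$config$input_side))
  fwd <- tm(predict(model, rast$val, type = "prob"))
  probs <- fwd$val[1, ]
  structure(list(label = names(probs)[which.max(probs)],
                 probs = probs,
                 window_samples = length(window$samples),
                 timings = c(preprocess = pre$sec, gram = gram$sec,
                             render = rast$sec, forward = fwd$sec)),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification> %s (confidence %.3f), %d-sample window, %.3f s total\n",
              x$label, max(x$probs), x$window_samples, sum(x$timings)))
  invisible(x)
}

#' Run a streaming identification session
#'
#' Loops `stabilize_and_capture` then `identify` over a stream source,
#' printing the predicted label and confidence per window and writing a
#' session log CSV (`timestamp`, `window`, `label`, `confidence`, one
#' column per stage timing). After the first window, subsequent windows
#' behave like the restart command of an interactive front end: a fresh
#' capture from the current stream position.
#'
#' @param source a `stream_source`.
#' @param model a fitted [ppgnet].
#' @param windows number of capture/identify cycles to run.
#' @param stabilization stabilization period in seconds applied before the
#'   first window; restarts use `restart_stabilization` (default 0:
#'   the sensor is already settled).
#' @param restart_stabilization stabilization seconds for windows after
#'   the first.
#' @param window window length in samples.
#' @param variant preprocessing variant.
#' @param log_path optional CSV path for the session log.
#' @param quiet suppress per-window console output.
#' @return data frame session log (invisibly when printing).
#' @export
run_session <- function(source, model, windows = 1, stabilization = 25,
                        restart_stabilization = 0, window = 300,
                        variant = "filtered", log_path = NULL, quiet = FALSE) {
  rows <- vector("list", windows)
  for (w in seq_len(windows)) {
    stab <- if (w == 1) stabilization else restart_stabilization
    sig <- stabilize_and_capture(source, stab, window)
    res <- identify(sig, model, variant)
    if (!quiet)
      cat(sprintf("[window %d] predicted %s (confidence %.3f)\n",
                  w, res$label, max(res$probs)))
    rows[[w]] <- data.frame(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                            window = w, label = res$label,
                            confidence = max(res$probs),
                            t_preprocess = res$timings[["preprocess"]],
                            t_gram = res$timings[["gram"]],
                            t_render = res$timings[["render"]],
                            t_forward = res$timings[["forward"]])
  }
  log <- do.call(rbind, rows)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  invisible(log)
}
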