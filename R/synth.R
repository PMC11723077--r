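#' Subject beat-morphology profile
#'
#' A `subject_profile` holds the per-subject parameters of the parametric
#' PPG beat model: one cardiac cycle is a sum of three Gaussian bumps
#' (systolic peak, dicrotic wave, diastolic wave) whose relative positions,
#' amplitudes and widths differ between subjects and constitute the
#' biometric identity emulated by the generator.
#'
#' @param subject_id character label for the subject.
#' @param heart_period cardiac cycle length in seconds; must lie in the
#'   physiological resting range \[0.5, 1.5\].
#' @param systolic_amp,dicrotic_amp,diastolic_amp relative amplitudes of the
#'   three components; `systolic_amp` must dominate the other two (the
#'   systolic peak is the maximum of the cycle).
#' @param systolic_pos,dicrotic_pos,diastolic_pos positions of the three
#'   components as fractions of the beat, strictly increasing in (0, 1).
#' @param systolic_width width (standard deviation) of the systolic bump in
#'   seconds; the dicrotic and diastolic widths are tied to it (0.6x and
#'   1.1x respectively).
#' @param baseline_level DC level of the raw signal, in ADC counts.
#' @param pulse_amplitude peak-to-baseline pulse excursion, in ADC counts.
#' @param jitter_sd standard deviation of per-beat timing jitter, seconds.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            heart_period = 0.9,
                            systolic_amp = 1.0, systolic_pos = 0.22,
                            systolic_width = 0.07,
                            dicrotic_amp = 0.15, dicrotic_pos = 0.5,
                            diastolic_amp = 0.4, diastolic_pos = 0.72,
                            baseline_level = 100000,
                            pulse_amplitude = 50000,
                            jitter_sd = 0.01) {
  p <- structure(
    list(subject_id = as.character(subject_id),
         heart_period = heart_period,
         systolic_amp = systolic_amp, systolic_pos = systolic_pos,
         systolic_width = systolic_width,
         dicrotic_amp = dicrotic_amp, dicrotic_pos = dicrotic_pos,
         diastolic_amp = diastolic_amp, diastolic_pos = diastolic_pos,
         baseline_level = baseline_level,
         pulse_amplitude = pulse_amplitude,
         jitter_sd = jitter_sd),
    class = "subject_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  with(p, {
    if (!(systolic_pos > 0 && systolic_pos < dicrotic_pos &&
          dicrotic_pos < diastolic_pos && diastolic_pos < 1))
      stopf("component positions must satisfy 0 < systolic < dicrotic < diastolic < 1")
    if (systolic_amp < dicrotic_amp || systolic_amp < diastolic_amp)
      stopf("systolic amplitude must dominate dicrotic and diastolic amplitudes")
    if (systolic_amp <= 0 || systolic_amp > 1)
      stopf("systolic_amp must lie in (0, 1]")
    if (heart_period < 0.5 || heart_period > 1.5)
      stopf("heart_period %.3f s outside the resting range [0.5, 1.5] s", heart_period)
    if (systolic_width <= 0 || jitter_sd < 0)
      stopf("systolic_width must be positive and jitter_sd non-negative")
  })
  invisible(p)
}

#' Draw a random subject profile
#'
#' Samples beat-model parameters from uniform ranges wide enough that
#' subjects remain distinguishable under the default measurement noise,
#' while every draw satisfies the profile invariants by construction.
#'
#' @param subject_id label for the subject.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a [subject_profile].
#' @export
make_subject_profile <- function(subject_id = "S01", seed = NULL) {
  draw <- function() {
    subject_profile(
      subject_id = subject_id,
      heart_period = runif(1, 0.7, 1.1),
      systolic_amp = runif(1, 0.85, 1.0),
      systolic_pos = runif(1, 0.16, 0.30),
      systolic_width = runif(1, 0.05, 0.09),
      dicrotic_amp = runif(1, 0.08, 0.22),
      dicrotic_pos = runif(1, 0.44, 0.56),
      diastolic_amp = runif(1, 0.28, 0.50),
      diastolic_pos = runif(1, 0.64, 0.80),
      baseline_level = runif(1, 60000, 140000),
      pulse_amplitude = runif(1, 30000, 70000),
      jitter_sd = runif(1, 0.005, 0.02))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s>  period %.2f s, peaks at %.2f/%.2f/%.2f of beat\n",
              x$subject_id, x$heart_period,
              x$systolic_pos, x$dicrotic_pos, x$diastolic_pos))
  invisible(x)
}

#' Construct a PPG signal object
#'
#' @param samples numeric vector of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject label.
#' @param adc_bits ADC resolution in bits (raw signals span
#'   \[0, 2^adc_bits - 1\]).
#' @param provenance one of `"raw"`, `"filtered"`, `"normalized"`.
#' @return an object of class `ppg_signal`.
#' @export
ppg_signal <- function(samples, sampling_rate = 50, subject_id = NA_character_,
                       adc_bits = 18, provenance = c("raw", "filtered", "normalized")) {
  provenance <- match.arg(provenance)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stopf("a ppg_signal needs at least one sample")
  if (provenance == "raw") {
    hi <- 2^adc_bits - 1
    if (any(samples != round(samples)) || any(samples < 0) || any(samples > hi))
      stopf("raw samples must be integers in [0, %d]", hi)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 subject_id = subject_id, adc_bits = adc_bits,
                 provenance = provenance),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal %s> %d samples @ %g Hz [%s], range [%g, %g]\n",
              x$subject_id, length(x$samples), x$sampling_rate, x$provenance,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' Synthesize one PPG beat
#'
#' Evaluates the three-bump beat model of a [subject_profile] over one
#' cardiac cycle: a unimodal rise to the systolic peak, a local minimum
#' (the dicrotic notch) between the systolic and diastolic components, and
#' a secondary diastolic wave. Values are in relative units (roughly
#' \[0, 1\]) before scaling to ADC counts.
#'
#' @param profile a [subject_profile].
#' @param sampling_rate sampling rate in Hz; must resolve at least 10
#'   samples per beat.
#' @param period optional beat period in seconds overriding
#'   `profile$heart_period` (used for per-beat jitter).
#' @return numeric vector of length `round(period * sampling_rate)`.
#' @export
synth_beat <- function(profile, sampling_rate = 50, period = NULL) {
  validate_profile(profile)
  if (is.null(period)) period <- profile$heart_period
  n <- round(period * sampling_rate)
  if (n < 10)
    stopf("sampling rate %g Hz resolves only %d samples per beat (< 10)",
          sampling_rate, n)
  t <- (seq_len(n) - 1) / n                      # fraction of the beat
  w_sys <- profile$systolic_width / period       # widths as beat fractions
  w_dic <- 0.6 * w_sys
  w_dia <- 1.1 * w_sys
  bump <- function(amp, pos, w) amp * exp(-(t - pos)^2 / (2 * w^2))
  bump(profile$systolic_amp,  profile$systolic_pos,  w_sys) +
    bump(profile$dicrotic_amp,  profile$dicrotic_pos,  w_dic) +
    bump(profile$diastolic_amp, profile$diastolic_pos, w_dia)
}

#' Generator configuration
#'
#' Defaults mirror the acquisition campaign the generator emulates:
#' 40 subjects, 80 recordings each, 300 samples per recording, 18-bit ADC
#' counts. The sampling rate defaults to 50 Hz so that a 300-sample record
#' covers about 6 s, i.e. 5-8 cardiac cycles.
#'
#' @param n_subjects number of subjects.
#' @param signals_per_subject recordings per subject.
#' @param signal_length samples per recording.
#' @param sampling_rate sampling rate in Hz.
#' @param noise_sd standard deviation of additive Gaussian measurement
#'   noise, in ADC counts.
#' @param adc_bits ADC resolution.
#' @param random_phase when `TRUE`, each recording starts at a uniformly
#'   random phase of the cardiac cycle instead of at a beat onset.
#'   Beat-aligned records (the default) keep recordings of the same
#'   subject directly comparable sample by sample.
#' @param seed master seed; one deterministic RNG stream is derived per
#'   subject, so adding subjects never perturbs existing ones.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 40, signals_per_subject = 80,
                             signal_length = 300, sampling_rate = 50,
                             noise_sd = 800, adc_bits = 18,
                             random_phase = FALSE, seed = 1) {
  for (v in c("n_subjects", "signals_per_subject", "signal_length"))
    if (!is_count(get(v))) stopf("%s must be a positive integer", v)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_subjects = n_subjects,
                 signals_per_subject = signals_per_subject,
                 signal_length = signal_length, sampling_rate = sampling_rate,
                 noise_sd = noise_sd, adc_bits = adc_bits,
                 random_phase = isTRUE(random_phase),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Synthesize one raw PPG recording
#'
#' Concatenates beats with per-beat timing jitter, scales to ADC counts
#' (`baseline_level + pulse_amplitude * beat`), adds i.i.d. Gaussian
#' measurement noise, clips to the ADC range and rounds to integers.
#' Recordings start at a beat onset unless `phase` (or the config's
#' `random_phase`) says otherwise. Consumes the caller's RNG stream (seed
#' it for reproducibility).
#'
#' @param profile a [subject_profile].
#' @param config a [generator_config].
#' @param phase capture onset as a fraction of the first beat in \[0, 1);
#'   `NULL` (default) means 0, or a uniform draw when the config sets
#'   `random_phase`.
#' @return a raw-provenance [ppg_signal] of length `config$signal_length`.
#' @export
synth_signal <- function(profile, config = generator_config(), phase = NULL) {
  L <- config$signal_length
  rate <- config$sampling_rate
  if (is.null(phase))
    phase <- if (isTRUE(config$random_phase)) runif(1) else 0
  samples <- numeric(0)
  first <- TRUE
  while (length(samples) < L) {
    period <- profile$heart_period +
      if (profile$jitter_sd > 0) rnorm(1, 0, profile$jitter_sd) else 0
    period <- max(period, 10 / rate)   # never below the resolvable minimum
    beat <- synth_beat(profile, rate, period = period)
    if (first) {
      beat <- beat[(floor(phase * length(beat)) + 1):length(beat)]
      first <- FALSE
    }
    samples <- c(samples, beat)
  }
  x <- samples[seq_len(L)]
  counts <- profile$baseline_level + profile$pulse_amplitude * x
  if (config$noise_sd > 0) counts <- counts + rnorm(L, 0, config$noise_sd)
  hi <- 2^config$adc_bits - 1
  counts <- round(pmin(pmax(counts, 0), hi))
  ppg_signal(counts, sampling_rate = rate, subject_id = profile$subject_id,
             adc_bits = config$adc_bits, provenance = "raw")
}

#' Generate a labelled multi-subject PPG dataset
#'
#' Draws one [subject_profile] per subject and `signals_per_subject` raw
#' recordings from each, using an independent per-subject RNG stream
#' derived from `config$seed`. The result is bit-identical for identical
#' configurations.
#'
#' @param config a [generator_config].
#' @return an object of class `ppg_dataset`: a list with elements
#'   `signals` (list of [ppg_signal]), `profiles`, `manifest` (data frame
#'   with `signal_id`, `subject_id`, `provenance`, `split`) and `config`.
#' @export
build_dataset <- function(config = generator_config()) {
  signals <- vector("list", config$n_subjects * config$signals_per_subject)
  profiles <- vector("list", config$n_subjects)
  ids <- character(length(signals))
  subjects <- character(length(signals))
  k <- 0
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    withr::with_seed(child_seed(config$seed, s), {
      profiles[[s]] <- make_subject_profile(sid)
      for (r in seq_len(config$signals_per_subject)) {
        k <- k + 1
        signals[[k]] <- synth_signal(profiles[[s]], config)
        ids[k] <- sprintf("%s_R%03d", sid, r)
        subjects[k] <- sid
      }
    })
  }
  names(profiles) <- vapply(profiles, `[[`, "", "subject_id")
  structure(list(signals = signals, profiles = profiles,
                 manifest = data.frame(signal_id = ids, subject_id = subjects,
                                       provenance = "raw", split = NA_character_,
                                       stringsAsFactors = FALSE),
                 config = config),
            class = "ppg_dataset")
}

#' Reconstruct the profile a dataset seed assigns to a subject
#'
#' Returns the same [subject_profile] that [build_dataset()] draws for
#' subject number `subject_index` under master seed `seed`, without
#' generating the dataset. Useful for replaying a known subject's stream.
#'
#' @param seed the generator master seed.
#' @param subject_index 1-based subject number.
#' @return a [subject_profile].
#' @export
dataset_profile <- function(seed, subject_index) {
  withr::with_seed(child_seed(seed, subject_index),
                   make_subject_profile(sprintf("S%02d", subject_index)))
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat(sprintf("<ppg_dataset> %d signals, %d subjects, %d samples each [%s]\n",
              length(x$signals), length(unique(x$manifest$subject_id)),
              length(x$signals[[1]]$samples),
              paste(unique(x$manifest$provenance), collapse = "+")))
  invisible(x)
}

#' @export
length.ppg_dataset <- function(x) length(x$signals)

#' Write / read a PPG dataset as CSV files
#'
#' One single-column CSV per recording (column `count`) plus a
#' `manifest.csv` (`filename`, `signal_id`, `subject_id`, `provenance`,
#' `split`, `sampling_rate`, `adc_bits`), mirroring a
#' spreadsheet-per-recording acquisition workflow in an open format.
#'
#' @param dataset a `ppg_dataset`.
#' @param dir directory to write to (created if missing).
#' @return `write_ppg_dataset` returns `dir` invisibly; `read_ppg_dataset`
#'   returns a `ppg_dataset` (without generator profiles).
#' @export
write_ppg_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$filename <- paste0(man$signal_id, ".csv")
  man$sampling_rate <- vapply(dataset$signals, `[[`, 0, "sampling_rate")
  man$adc_bits <- vapply(dataset$signals, `[[`, 0, "adc_bits")
  for (i in seq_along(dataset$signals))
    write.csv(data.frame(count = dataset$signals[[i]]$samples),
              file.path(dir, man$filename[i]), row.names = FALSE)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ppg_dataset
#' @export
read_ppg_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  signals <- lapply(seq_len(nrow(man)), function(i) {
    counts <- read.csv(file.path(dir, man$filename[i]))$count
    ppg_signal(counts, sampling_rate = man$sampling_rate[i],
               subject_id = man$subject_id[i], adc_bits = man$adc_bits[i],
               provenance = man$provenance[i])
  })
  structure(list(signals = signals, profiles = NULL,
                 manifest = man[, c("signal_id", "subject_id", "provenance", "split")],
                 config = NULL),
            class = "ppg_dataset")
}

#' Long-format export of a PPG dataset
#'
#' @param dataset a `ppg_dataset`.
#' @param path CSV path; columns `signal_id`, `sample_index`, `value`,
#'   `subject_id`.
#' @export
write_ppg_long <- function(dataset, path) {
  dfs <- lapply(seq_along(dataset$signals), function(i) {
    s <- dataset$signals[[i]]
    data.frame(signal_id = dataset$manifest$signal_id[i],
               sample_index = seq_along(s$samples),
               value = s$samples,
               subject_id = s$subject_id)
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppg_long
#' @export
read_ppg_long <- function(path, sampling_rate = 50, adc_bits = 18) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$signal_id)
  signals <- lapply(ids, function(id) {
    rows <- long[long$signal_id == id, ]
    rows <- rows[order(rows$sample_index), ]
    ppg_signal(rows$value, sampling_rate = sampling_rate,
               subject_id = rows$subject_id[1], adc_bits = adc_bits,
               provenance = "raw")
  })
  structure(list(signals = signals, profiles = NULL,
                 manifest = data.frame(
                   signal_id = ids,
                   subject_id = vapply(signals, `[[`, "", "subject_id"),
                   provenance = "raw", split = NA_character_,
                   stringsAsFactors = FALSE),
                 config = NULL),
            class = "ppg_dataset")
}
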