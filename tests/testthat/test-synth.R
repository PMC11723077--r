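test_that("profile draws are reproducible, distinct across seeds, and valid", {
  p1 <- make_subject_profile("A", seed = 5)
  p2 <- make_subject_profile("A", seed = 5)
  expect_identical(p1, p2)

  q <- make_subject_profile("A", seed = 6)
  fields <- setdiff(names(p1), "subject_id")
  expect_true(any(vapply(fields, function(f) !identical(p1[[f]], q[[f]]), TRUE)))

  for (s in 1:200) {
    p <- make_subject_profile(seed = s)
    expect_true(p$systolic_pos < p$dicrotic_pos)
    expect_true(p$dicrotic_pos < p$diastolic_pos)
    expect_true(p$systolic_amp >= p$dicrotic_amp)
    expect_true(p$systolic_amp >= p$diastolic_amp)
    expect_true(p$heart_period >= 0.5 && p$heart_period <= 1.5)
  }
})

test_that("profile invariants are enforced at construction", {
  expect_error(subject_profile(systolic_pos = 0.6, dicrotic_pos = 0.5),
               "positions")
  expect_error(subject_profile(systolic_amp = 0.3, diastolic_amp = 0.5),
               "dominate")
  expect_error(subject_profile(heart_period = 2.0), "resting range")
})

test_that("synthesized beats have the landmark geometry", {
  p <- make_subject_profile(seed = 1)
  b <- synth_beat(p, 100)
  expect_length(b, round(p$heart_period * 100))
  # global maximum at the systolic peak
  expect_equal(which.max(b), round(p$systolic_pos * length(b)) + 1,
               tolerance = 0, ignore_attr = TRUE)
  # a local minimum (dicrotic notch) between systolic and diastolic peaks
  i_sys <- which.max(b)
  i_dia <- round(p$diastolic_pos * length(b)) + 1
  expect_true(b[i_dia] > b[i_dia - 3] || b[i_dia] > b[i_dia + 3]) # secondary wave
  between <- b[i_sys:i_dia]
  expect_true(min(between) < b[i_sys] && min(between) < b[i_dia])

  # degenerate single-component beat peaks where the systolic bump sits
  pd <- p; pd$dicrotic_amp <- 0; pd$diastolic_amp <- 0
  bd <- synth_beat(pd, 100)
  expect_lte(abs(which.max(bd) - 1 - round(pd$systolic_pos * length(bd))), 1)

  # sampling too coarse to resolve the landmarks
  expect_error(synth_beat(p, 5), "< 10")
})

test_that("beats at doubled rate agree with the coarse grid after downsampling", {
  p <- make_subject_profile(seed = 2)
  b1 <- synth_beat(p, 50)
  b2 <- synth_beat(p, 100)
  peak1 <- which.max(b1)
  peak2 <- which.max(b2)
  expect_lte(abs((peak2 - 1) / 2 - (peak1 - 1)), 1)
})

test_that("raw signals are integer, in the 18-bit ADC range, and periodic without noise", {
  p <- make_subject_profile(seed = 3)
  cfg <- generator_config(n_subjects = 1, signals_per_subject = 1,
                          noise_sd = 0, seed = 1)
  p0 <- p; p0$jitter_sd <- 0
  s <- synth_signal(p0, cfg)
  expect_length(s$samples, cfg$signal_length)
  expect_true(all(s$samples == round(s$samples)))
  expect_true(all(s$samples >= 0 & s$samples <= 2^18 - 1))
  period <- round(p0$heart_period * cfg$sampling_rate)
  lagged <- abs(s$samples[seq_len(300 - period)] - s$samples[(period + 1):300])
  expect_lte(max(lagged), 1)   # equal within integer rounding
})

test_that("datasets are balanced, labelled and bit-reproducible", {
  cfg <- generator_config(n_subjects = 3, signals_per_subject = 5,
                          signal_length = 150, seed = 9)
  ds <- build_dataset(cfg)
  expect_length(ds$signals, 15)
  expect_equal(unname(table(ds$manifest$subject_id)), rep(5L, 3),
               ignore_attr = TRUE)
  expect_identical(ds, build_dataset(cfg))

  one <- build_dataset(generator_config(1, 1, 100, seed = 2))
  expect_length(one$signals, 1)

  # adding a subject leaves existing subjects' signals untouched
  bigger <- build_dataset(generator_config(4, 5, 150, seed = 9))
  expect_identical(ds$signals[[1]]$samples, bigger$signals[[1]]$samples)
  expect_identical(ds$signals[[15]]$samples, bigger$signals[[15]]$samples)
})

test_that("same-subject signals are closer than cross-subject signals at low noise", {
  cfg <- generator_config(n_subjects = 5, signals_per_subject = 6,
                          signal_length = 200, noise_sd = 50, seed = 21)
  ds <- build_dataset(cfg)
  sig <- function(i) minmax_normalize(ds$signals[[i]])$samples
  subj <- ds$manifest$subject_id
  set.seed(7)
  within <- c(); between <- c()
  for (k in 1:150) {
    i <- sample(length(ds$signals), 1); j <- sample(length(ds$signals), 1)
    if (i == j) next
    d <- mean((sig(i) - sig(j))^2)
    if (subj[i] == subj[j]) within <- c(within, d) else between <- c(between, d)
  }
  expect_gt(length(within), 20)
  expect_lt(mean(within), mean(between))
})

test_that("dataset CSV round-trips preserve samples and labels", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(2, 2, 120, seed = 4)
  ds <- build_dataset(cfg)
  write_ppg_dataset(ds, dir)
  back <- read_ppg_dataset(dir)
  expect_equal(length(back$signals), length(ds$signals))
  expect_identical(back$signals[[3]]$samples, ds$signals[[3]]$samples)
  expect_identical(back$manifest$subject_id, ds$manifest$subject_id)

  longfile <- file.path(dir, "long.csv")
  write_ppg_long(ds, longfile)
  back2 <- read_ppg_long(longfile)
  expect_identical(back2$signals[[4]]$samples, ds$signals[[4]]$samples)
})

test_that("dataset_profile reproduces the profiles build_dataset draws", {
  cfg <- generator_config(3, 2, 120, seed = 31)
  ds <- build_dataset(cfg)
  expect_identical(dataset_profile(31, 2), ds$profiles[[2]])
})
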