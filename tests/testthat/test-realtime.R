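# A shared micro model fitted once for the streaming tests.
fitted_micro <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gd <- tiny_gram_set(n_subjects = 3, per_subject = 30, side = 32, seed = 23)
      sp <- split_dataset(gd, 0.8, seed = 23)
      cache <<- list(
        fit = ppgnet(sp$train, config = micro_config(3, side = 32),
                     setting = train_setting(2),
                     epochs = 25, patience = 10, seed = 23),
        test = sp$test)
    }
    cache
  }
})

test_that("stabilization discards the exact sample count before capture", {
  src <- stream_from_vector(seq_len(5000), sampling_rate = 50)
  sig <- stabilize_and_capture(src, stabilization = 25, window = 300)
  expect_equal(sig$samples[1], 1251)   # 25 s x 50 Hz = 1250 discarded
  expect_length(sig$samples, 300)
  expect_equal(src$pos(), 1550)

  src0 <- stream_from_vector(seq_len(400), sampling_rate = 50)
  sig0 <- stabilize_and_capture(src0, stabilization = 0, window = 300)
  expect_equal(sig0$samples[1], 1)

  # arbitrary (rate, duration) pairs discard round(rate * duration)
  for (rate in c(25, 80)) for (stab in c(1.3, 4.7)) {
    s <- stream_from_vector(seq_len(2000), sampling_rate = rate)
    got <- stabilize_and_capture(s, stab, window = 10)
    expect_equal(got$samples[1], round(stab * rate) + 1)
  }

  expect_error(stabilize_and_capture(stream_from_vector(1:100), 25, 300),
               "exhausted")
})

test_that("file and generator stream sources replay deterministically", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "stream.csv")
  write.csv(data.frame(count = 101:400), path, row.names = FALSE)
  src <- stream_from_file(path, sampling_rate = 50)
  expect_equal(src$take(5), 101:105)
  expect_equal(src$take(2), 106:107)

  p <- make_subject_profile(seed = 40)
  g1 <- stream_from_generator(p, generator_config(seed = 1), seed = 77)
  g2 <- stream_from_generator(p, generator_config(seed = 1), seed = 77)
  a <- g1$take(500)
  expect_identical(a, g2$take(500))
  expect_true(all(a >= 0 & a <= 2^18 - 1))
})

test_that("streaming identification equals the offline pipeline on the same window", {
  mf <- fitted_micro()
  p <- dataset_profile(23, 1)
  src <- stream_from_generator(p, generator_config(noise_sd = 200, seed = 1),
                               seed = 5)
  win <- stabilize_and_capture(src, stabilization = 2, window = 300)
  res <- identify(win, mf$fit, variant = "filtered")
  expect_s3_class(res, "identification_result")
  expect_equal(sum(res$probs), 1, tolerance = 1e-6)
  expect_equal(res$label, names(res$probs)[which.max(res$probs)])
  expect_equal(res$window_samples, 300)
  expect_true(all(res$timings >= 0))

  # offline route on the identical window
  offline <- predict(mf$fit,
                     render_gram(signal_gram(preprocess_pipeline(win, "filtered")),
                                 side = mf$fit$config$input_side),
                     type = "prob")
  expect_equal(unname(res$probs), unname(offline[1, ]), tolerance = 1e-12)

  const <- ppg_signal(rep(5L, 300), provenance = "raw")
  expect_error(identify(const, mf$fit), "degenerate")
})

test_that("low-noise windows from a training subject are identified correctly", {
  mf <- fitted_micro()
  hits <- 0; trials <- 20
  for (t in seq_len(trials)) {
    subj <- (t %% 3) + 1
    p <- dataset_profile(23, subj)
    src <- stream_from_generator(p,
                                 generator_config(signal_length = 120,
                                                  noise_sd = 200, seed = 1),
                                 seed = 100 + t)
    # window length matches the 120-sample records the model was trained on
    win <- stabilize_and_capture(src, stabilization = 0, window = 120,
                                 subject_id = sprintf("S%02d", subj))
    res <- identify(win, mf$fit, variant = "raw")
    if (res$label == win$subject_id) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})

test_that("sessions log one row per window with the documented schema", {
  mf <- fitted_micro()
  dir <- withr::local_tempdir()
  p <- dataset_profile(23, 2)
  src <- stream_from_generator(p, generator_config(noise_sd = 200, seed = 1),
                               seed = 9)
  log_path <- file.path(dir, "session.csv")
  log <- run_session(src, mf$fit, windows = 3, stabilization = 1,
                     window = 300, variant = "raw", log_path = log_path,
                     quiet = TRUE)
  expect_equal(nrow(log), 3)
  expect_equal(names(log),
               c("timestamp", "window", "label", "confidence",
                 "t_preprocess", "t_gram", "t_render", "t_forward"))
  expect_true(all(log$confidence > 0 & log$confidence <= 1))
  expect_equal(nrow(read.csv(log_path)), 3)

  # restart semantics: the second window continues from the stream position
  src2 <- stream_from_vector(seq_len(1000), sampling_rate = 50)
  run1 <- stabilize_and_capture(src2, 0, 300)
  run2 <- stabilize_and_capture(src2, 0, 300)
  expect_equal(src2$pos(), 600)
  expect_equal(run2$samples[1], 301)   # fresh capture, not a replay
})

test_that("fitted models survive a plain-text save/load round trip", {
  mf <- fitted_micro()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.txt")
  save_ppgnet(mf$fit, path)
  back <- load_ppgnet(path)
  expect_equal(back$classes, mf$fit$classes)
  probs1 <- predict(mf$fit, mf$test, type = "prob")
  probs2 <- predict(back, mf$test, type = "prob")
  expect_equal(probs1, probs2, tolerance = 1e-12)
})
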