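test_that("the three preset settings carry the documented hyperparameters", {
  s1 <- train_setting(1); s2 <- train_setting(2); s3 <- train_setting(3)
  expect_equal(c(s1$batch_size, s2$batch_size, s3$batch_size), c(16, 32, 64))
  expect_equal(c(s1$optimizer, s2$optimizer, s3$optimizer),
               c("sgd", "adam", "rmsprop"))
  expect_equal(c(s1$learning_rate, s2$learning_rate, s3$learning_rate),
               c(0.01, 0.001, 0.0001))
  expect_error(train_setting(4), "1, 2 or 3")
})

test_that("stratified splitting partitions each subject at the requested fraction", {
  gd <- tiny_gram_set(n_subjects = 3, per_subject = 10)
  sp <- split_dataset(gd, 0.8, seed = 2)
  expect_length(sp$train, 24)
  expect_length(sp$test, 6)
  expect_equal(unname(table(sp$train$labels)), rep(8L, 3), ignore_attr = TRUE)
  # disjoint and exhaustive partition
  expect_length(intersect(sp$train$meta$record_id, sp$test$meta$record_id), 0)
  expect_setequal(c(sp$train$meta$record_id, sp$test$meta$record_id),
                  gd$meta$record_id)
  # deterministic under seed
  sp2 <- split_dataset(gd, 0.8, seed = 2)
  expect_identical(sp$train$meta$record_id, sp2$train$meta$record_id)

  half <- split_dataset(tiny_gram_set(2, 2), 0.5, seed = 1)
  expect_equal(unname(table(half$train$labels)), rep(1L, 2), ignore_attr = TRUE)

  single <- tiny_gram_set(2, 4)
  lone <- ppgid:::subset_gram_dataset(single, c(1, 5, 6, 7, 8))
  expect_error(split_dataset(lone, 0.8), "at least 2")
  expect_error(split_dataset(gd, 1.2), "train_frac")
})

test_that("training learns a small separable problem and records history", {
  gd <- tiny_gram_set(n_subjects = 4, per_subject = 8, side = 16, seed = 13)
  sp <- split_dataset(gd, 0.75, seed = 13)
  fit <- ppgnet(sp$train, config = micro_config(4), setting = train_setting(2),
                epochs = 25, patience = 10, val_frac = 0.15, seed = 13)
  expect_s3_class(fit, "ppgnet")
  h <- fit$history
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss", "val_acc")
                  %in% names(h)))
  expect_equal(nrow(h), fit$stopped_epoch)
  expect_gte(max(h$train_acc), 0.95)
  # refit with the same seed is identical
  fit2 <- ppgnet(sp$train, config = micro_config(4), setting = train_setting(2),
                 epochs = 25, patience = 10, val_frac = 0.15, seed = 13)
  expect_identical(fit$params, fit2$params)
  expect_equal(fit$history, fit2$history)

  hist_path <- file.path(withr::local_tempdir(), "history.csv")
  write_training_history(fit, hist_path)
  hcsv <- read.csv(hist_path)
  expect_equal(nrow(hcsv), fit$stopped_epoch)
  expect_true(all(c("run_id", "seed", "setting_id", "epoch", "val_loss")
                  %in% names(hcsv)))

  pred <- predict(fit, sp$test)
  expect_s3_class(pred, "factor")
  expect_length(pred, length(sp$test))
  probs <- predict(fit, sp$test, type = "prob")
  expect_equal(rowSums(probs), rep(1, length(sp$test)), tolerance = 1e-6)

  expect_error(ppgnet(array(0, c(16, 16, 0)), character(0)), "empty|labels")
})

test_that("early stopping halts at epoch patience + 1 when the loss never improves", {
  gd <- tiny_gram_set(n_subjects = 2, per_subject = 4, side = 16, seed = 3)
  sp <- split_dataset(gd, 0.5, seed = 3)
  # zero learning rate and frozen normalization statistics: the validation
  # loss never improves after epoch 1
  frozen <- train_setting(1)
  frozen$learning_rate <- 0
  cfg <- micro_config(2)
  cfg$bn_momentum <- 1
  fit <- ppgnet(sp$train, config = cfg, setting = frozen,
                epochs = 25, patience = 10, val_frac = 0.25, seed = 3)
  expect_equal(fit$stopped_epoch, 11)
  expect_equal(fit$best_epoch, 1)
})

test_that("evaluation metrics match their definitions and an independent implementation", {
  # hand-computed two-class example
  rep2 <- eval_report(matrix(c(8, 1, 2, 9), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(rep2$per_class$precision, c(8 / 9, 9 / 11))
  expect_equal(rep2$per_class$recall, c(0.8, 0.9))
  expect_equal(rep2$accuracy, 17 / 20)
  expect_equal(sum(rep2$confusion), 20)
  expect_equal(rep2$accuracy, sum(diag(rep2$confusion)) / sum(rep2$confusion))

  # cross-check against caret on a random 4-class confusion
  set.seed(31)
  truth <- factor(sample(letters[1:4], 200, replace = TRUE))
  pred <- factor(ifelse(runif(200) < 0.7, as.character(truth),
                        sample(letters[1:4], 200, replace = TRUE)),
                 levels = levels(truth))
  rep4 <- eval_report(table(truth = truth, predicted = pred))
  cm <- caret::confusionMatrix(pred, truth, mode = "prec_recall")
  expect_equal(unname(rep4$per_class$precision),
               unname(cm$byClass[, "Precision"]), tolerance = 1e-12)
  expect_equal(unname(rep4$per_class$recall),
               unname(cm$byClass[, "Recall"]), tolerance = 1e-12)
  expect_equal(unname(rep4$per_class$f1), unname(cm$byClass[, "F1"]),
               tolerance = 1e-12)
  expect_equal(unname(rep4$accuracy), unname(cm$overall["Accuracy"]),
               tolerance = 1e-12)

  # balanced supports make macro and weighted averages coincide
  bal <- eval_report(matrix(c(9, 1, 0, 1, 8, 1, 0, 1, 9), 3, 3))
  expect_equal(bal$macro, bal$weighted)

  # single predicted class: undefined precisions score 0 with a warning
  expect_warning(one <- eval_report(matrix(c(5, 3, 0, 0), 2, 2)), "convention")
  expect_equal(one$per_class$precision, c(5 / 8, 0))

  # weighted average with a single represented class equals that class's metric
  expect_warning(solo <- eval_report(matrix(c(6, 0, 1, 0), 2, 2)), "convention")
  expect_equal(unname(solo$weighted["recall"]), 6 / 7)
})

test_that("evaluation reports export to CSV with macro and weighted footers", {
  dir <- withr::local_tempdir()
  rep2 <- eval_report(matrix(c(8, 1, 2, 9), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  path <- file.path(dir, "report.csv")
  write_eval_report(rep2, path, confusion_path = file.path(dir, "cm.csv"))
  out <- read.csv(path)
  expect_equal(nrow(out), 4)
  expect_equal(out$class[3:4], c("macro_avg", "weighted_avg"))
  cm <- read.csv(file.path(dir, "cm.csv"))
  expect_equal(sum(cm), 20)
})

test_that("the ablation harness emits one row per setting-variant cell, reproducibly", {
  cfg <- generator_config(n_subjects = 2, signals_per_subject = 4,
                          signal_length = 120, noise_sd = 200, seed = 17)
  ds <- build_dataset(cfg)
  tab <- ablation(ds, settings = list(train_setting(2)),
                  variants = c("raw", "filtered"), side = 16,
                  config = micro_config(2, 16), epochs = 2, patience = 2,
                  seed = 17)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$variant, c("raw", "filtered"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  tab2 <- ablation(ds, settings = list(train_setting(2)),
                   variants = c("raw", "filtered"), side = 16,
                   config = micro_config(2, 16), epochs = 2, patience = 2,
                   seed = 17)
  expect_equal(tab, tab2)
})
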