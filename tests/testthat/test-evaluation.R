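test_that("stratified hold-out splits are balanced, disjoint and seeded", {
  y <- factor(rep(paste0("w", 1:4), each = 20))
  sp <- holdout_split(y, 0.5, seed = 3)
  expect_equal(length(sp$train), 40)
  expect_equal(length(sp$test), 40)
  expect_equal(unname(table(y[sp$train])), rep(10L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(y[sp$test])), rep(10L, 4), ignore_attr = TRUE)
  expect_equal(sort(c(sp$train, sp$test)), 1:80)
  expect_identical(holdout_split(y, 0.5, seed = 3), sp)
  # different seeds give different splits with overwhelming probability
  expect_false(identical(holdout_split(y, 0.5, seed = 4)$train, sp$train))
  expect_error(holdout_split(factor(c("a", "b", "b")), 0.5), "fewer than 2")
})

test_that("confusion accuracy and mean/SD arithmetic are exact", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(accuracy_from_confusion(cm), 100 * 2 / 3)
  expect_equal(accuracy_from_confusion(t(cm)), 100 * 2 / 3)  # orientation
  expect_equal(accuracy_from_confusion(diag(5) * 7), 100)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
  # constant predictor on 4 balanced classes sits at chance
  cmc <- confusion_matrix(rep("a", 40), rep(c("a", "b", "c", "d"), 10))
  expect_equal(accuracy_from_confusion(cmc), 25)
  ms <- mean_sd(c(0, 100))
  expect_equal(ms$mean, 50)
  expect_equal(ms$sd, 70.71, tolerance = 1e-4)
  expect_equal(mean_sd(rep(3.3, 5))$sd, 0)
  expect_equal(mean_sd(7)$sd, 0)
  expect_error(mean_sd(numeric(0)), "non-empty")
})

test_that("repeated hold-out reports what it measured", {
  # trivially separable classes: every split classifies perfectly
  d <- make_blobs(10, rbind(c(0, 0), c(50, 50)), sd = 0.3, seed = 5)
  data <- enose_dataset(d$X, d$labels)
  r <- repeated_holdout_evaluate(data, extractor_spec("none"),
                                 repeats = 4, seed = 9)
  expect_equal(r$mean_accuracy, 100)
  expect_equal(r$sd_accuracy, 0)
  expect_equal(length(r$per_split_accuracy), 4)
  expect_equal(r$mean_accuracy, mean(r$per_split_accuracy))
  expect_equal(length(r$confusions), 4)
  # confusion totals equal the test-set size
  expect_equal(sum(r$confusions[[1]]), 10)
  # reproducible under the same seed
  r2 <- repeated_holdout_evaluate(data, extractor_spec("none"),
                                  repeats = 4, seed = 9)
  expect_identical(r$per_split_accuracy, r2$per_split_accuracy)
})

test_that("accuracy from the confusion matrix matches raw predictions", {
  d <- make_blobs(12, rbind(c(0, 0), c(2, 1), c(-1, 2)), sd = 0.8,
                  seed = 13)
  data <- enose_dataset(d$X, d$labels)
  r <- repeated_holdout_evaluate(data, extractor_spec("fda"),
                                 repeats = 3, seed = 2)
  for (i in 1:3)
    expect_equal(accuracy_from_confusion(r$confusions[[i]]),
                 r$per_split_accuracy[i])
})

test_that("batch transfer reports one accuracy per held-out batch", {
  cfg <- drift_sensor_config(samples_per_batch = 40)
  d <- simulate_drift_dataset(cfg, seed = 6)
  r <- batch_transfer_evaluate(d, extractor_spec("none"), seed = 1)
  expect_equal(length(r$per_batch_accuracy), 4)
  expect_named(r$per_batch_accuracy, as.character(2:5))
  expect_equal(r$mean_accuracy, mean(r$per_batch_accuracy),
               tolerance = 1e-12)
  expect_error(batch_transfer_evaluate(d, extractor_spec("none"),
                                       train_batch = "nope"),
               "unknown training batch")
  # without batch labels the protocol refuses to run
  expect_error(batch_transfer_evaluate(enose_dataset(d$X, d$labels),
                                       extractor_spec("none")), "batch")
})

test_that("a zero-drift control transfers cleanly across batches", {
  cfg <- drift_sensor_config(samples_per_batch = 40, drift_gain_sd = 0,
                             drift_offset_sd = 0)
  d <- simulate_drift_dataset(cfg, seed = 7)
  r <- batch_transfer_evaluate(d, extractor_spec("none"), seed = 2)
  expect_true(all(r$per_batch_accuracy > 90))
  expect_lt(diff(range(r$per_batch_accuracy)), 10)
})

test_that("strong drift in the designated batch drags its accuracy down", {
  cfg <- drift_sensor_config(samples_per_batch = 40, drift_gain_sd = 0.12,
                             drift_offset_sd = 0.12, high_drift_mult = 4)
  d <- simulate_drift_dataset(cfg, seed = 11)
  r <- batch_transfer_evaluate(d, extractor_spec("none"), seed = 3)
  expect_equal(names(which.min(r$per_batch_accuracy)), "5")
})

test_that("published column averages equal the mean of their batch entries", {
  tab <- reference_batch_accuracies()
  for (tb in unique(tab$table)) {
    sub <- tab[tab$table == tb, ]
    for (s in unique(sub$setting)) {
      col <- sub[sub$setting == s, ]
      m <- mean_sd(col$accuracy[col$batch != "average"])$mean
      expect_equal(round_half_up(m, 2),
                   col$accuracy[col$batch == "average"],
                   info = paste(tb, s))
    }
  }
})
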