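toy_windows <- function(n = 200, len = 200, seed = 1) {
  # linearly separable construction: events carry a centered pulse
  withr::with_seed(seed, {
    w <- matrix(rnorm(n * len, sd = 0.3), n, len)
    labels <- rep(c(1L, 0L), length.out = n)
    pulse <- 5 * exp(-abs(seq_len(len) - len / 2) / 8)
    w[labels == 1, ] <- sweep(w[labels == 1, , drop = FALSE], 2, pulse, "+")
    structure(list(windows = w, labels = labels, window_len = len,
                   event_noise_ratio = 1, sampling_rate = 20000),
              class = "psc_windows")
  })
}

test_that("the classifier separates linearly separable toy windows quickly", {
  win <- toy_windows()
  res <- train_detector(win, model_config(window_len = 200, channels = c(8, 16),
                                          batch_size = 32, max_epochs = 10,
                                          patience = 10, seed = 2))
  expect_gte(max(res$history$train_acc), 0.99)
  expect_lte(nrow(res$history), 10)
})

test_that("training is deterministic and the stratified split honors the fraction", {
  win <- toy_windows(n = 100)
  cfg <- model_config(window_len = 200, channels = c(4), max_epochs = 3, seed = 4)
  a <- train_detector(win, cfg)
  b <- train_detector(win, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_equal(a$model$fingerprint$n_val, 20)   # 20% of 100
  expect_error(train_detector(
    structure(list(windows = win$windows, labels = rep(1L, 100),
                   window_len = 200, sampling_rate = 20000),
              class = "psc_windows"), cfg), "both classes")
})

test_that("evaluation yields AUC 1 for a separating model and ~0.5 under label permutation", {
  win <- toy_windows(n = 300)
  res <- train_detector(
    win, model_config(window_len = 200, channels = c(8), batch_size = 32,
                      max_epochs = 15, patience = 15, seed = 6))
  ev <- evaluate_detector(res$model, win)
  expect_gte(ev$auc, 0.999)
  expect_true(all(diff(ev$roc$tpr) >= 0))
  expect_true(all(diff(ev$roc$fpr) >= 0))
  shuffled <- win
  shuffled$labels <- withr::with_seed(9, sample(win$labels))
  ev2 <- evaluate_detector(res$model, shuffled)
  expect_lt(abs(ev2$auc - 0.5), 0.07)
  one_class <- win; one_class$labels <- rep(1L, length(win$labels))
  expect_error(evaluate_detector(res$model, one_class), "single class")
})

test_that("sliding detection finds events, and extreme thresholds empty the table", {
  res <- small_test_model()
  sim <- simulate_trace(synthetic_spec(duration = 20, rate = 2, mode = "sIPSC",
                                       seed = 71))
  ev <- detect_ml(sim$trace, res$model)
  sc <- score_detection(sim$truth, ev, match_config(tolerance = 3))
  expect_gt(sc$recall, 0.8)
  expect_gt(sc$precision, 0.9)
  empty <- detect_ml(sim$trace, res$model,
                     ml_detect_config(probability_threshold = 1))
  expect_equal(nrow(empty), 0)
})

test_that("detection is invariant to DC offset and monotone in the probability threshold", {
  res <- small_test_model()
  sim <- simulate_trace(synthetic_spec(duration = 10, rate = 2, mode = "sIPSC",
                                       seed = 72))
  ev0 <- suppressWarnings(detect_ml(sim$trace, res$model))
  shifted <- trace(sim$trace$samples + 120, 20000, mode = "sIPSC",
                   recording_id = sim$trace$meta$recording_id)
  ev1 <- suppressWarnings(detect_ml(shifted, res$model))
  expect_equal(ev0$peak_time, ev1$peak_time)
  counts <- vapply(c(0.2, 0.5, 0.9), function(th)
    nrow(detect_ml(sim$trace, res$model,
                   ml_detect_config(probability_threshold = th))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rate mismatches are caught and resampling preserves band-limited content", {
  res <- small_test_model()
  tr10 <- trace(sin(2 * pi * 50 * (0:9999) / 10000), 10000, mode = "sIPSC")
  expect_error(detect_ml(tr10, res$model), "resample")
  up <- resample_for_model(tr10, 20000)
  expect_equal(length(up$samples), 20000)
  expect_equal(max(up$samples[5000:15000]), 1, tolerance = 0.01)
  expect_identical(resample_for_model(tr10, 10000), tr10)
  expect_error(detect_ml(trace(rnorm(100), 20000, mode = "sIPSC"), res$model),
               "shorter")
})
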