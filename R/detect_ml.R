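# Supervised window-classifier detector: train a small 1-D CNN on labeled
# windows, then slide it along a recording and turn suprathreshold
# probability runs into events.

#' CNN model configuration
#'
#' Defaults: three conv blocks (16/32/64 channels, kernel 9, max-pool 2)
#' over 600-sample windows (30 ms at 20 kHz), global average pooling and a
#' sigmoid head; binary cross-entropy loss, Adam (learning rate 1e-3), up
#' to 100 epochs with a 20% stratified hold-out and early stopping on
#' validation loss.
#'
#' @param window_len Window length, samples.
#' @param channels Integer vector of conv-block channel counts.
#' @param kernel Convolution kernel size, samples.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @param validation_fraction Stratified hold-out fraction in (0, 1).
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); `Inf` disables early stopping.
#' @param seed Integer seed for init, split and shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(window_len = 600, channels = c(16, 32, 64),
                         kernel = 9, learning_rate = 1e-3, max_epochs = 100,
                         batch_size = 256, validation_fraction = 0.2,
                         patience = 10, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("`validation_fraction` must be in (0, 1)")
  if (max_epochs < 1) stopf("`max_epochs` must be >= 1")
  structure(list(window_len = as.integer(window_len),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 patience = patience, seed = as.integer(seed)),
            class = "model_config")
}

#' Train the CNN window classifier
#'
#' Performs a stratified split into training and validation sets, trains
#' with minibatch Adam on binary cross-entropy, records per-epoch training
#' and validation loss and accuracy, stops early when validation loss stops
#' improving, and retains the parameters of the best validation epoch.
#'
#' @param windows A `psc_windows` set from [extract_training_windows()].
#' @param config A [model_config()].
#' @return A list with `model` (class `psc_cnn`) and `history` (data.frame
#'   with epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_detector <- function(windows, config = model_config()) {
  if (!inherits(windows, "psc_windows")) stopf("`windows` must be a psc_windows set")
  if (length(unique(windows$labels)) < 2L)
    stopf("training windows must contain both classes")
  if (ncol(windows$windows) != config$window_len)
    stopf("window length %d does not match config window_len %d",
          ncol(windows$windows), config$window_len)
  x <- standardize_windows(windows$windows)
  y <- as.numeric(windows$labels)
  with_seed(config$seed, {
    # stratified hold-out
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      n_val <- round(length(ix) * config$validation_fraction)
      sample(ix, n_val)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_along(y), val_idx)
    xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
    params <- init_cnn_params(config)
    state <- list(conv = vector("list", length(config$channels)), dense = list())
    hist <- data.frame()
    best <- list(loss = Inf, params = params, epoch = 0L)
    t_step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(xt))
      tr_loss <- 0; tr_n <- 0; tr_correct <- 0
      for (b0 in seq(1L, nrow(xt), by = config$batch_size)) {
        bi <- ord[b0:min(nrow(xt), b0 + config$batch_size - 1L)]
        fw <- cnn_forward(params, xt[bi, , drop = FALSE], config, keep_cache = TRUE)
        p <- sigmoid(fw$logits)
        loss <- bce_from_logits(fw$logits, yt[bi])
        dz <- (p - yt[bi]) / length(bi)
        grads <- cnn_backward(params, fw, dz, config)
        t_step <- t_step + 1L
        st <- adam_step(params, grads, state, config$learning_rate, t_step)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + loss * length(bi); tr_n <- tr_n + length(bi)
        tr_correct <- tr_correct + sum((p > 0.5) == (yt[bi] > 0.5))
      }
      zv <- predict_logits(params, xv, config)
      val_loss <- bce_from_logits(zv, yv)
      val_acc <- mean((sigmoid(zv) > 0.5) == (yv > 0.5))
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss / tr_n,
                                     train_acc = tr_correct / tr_n,
                                     val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss - 1e-6) best <- list(loss = val_loss, params = params, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
    model <- structure(list(params = best$params, config = config,
                            sampling_rate = windows$sampling_rate,
                            fingerprint = list(
                              n_windows = length(y), n_val = length(val_idx),
                              seed = config$seed,
                              data_sum = sum(windows$windows))),
                       class = "psc_cnn")
    list(model = model, history = hist)
  })
}

predict_logits <- function(params, x, config, chunk = 1024L) {
  out <- numeric(nrow(x))
  for (b0 in seq(1L, nrow(x), by = chunk)) {
    bi <- b0:min(nrow(x), b0 + chunk - 1L)
    out[bi] <- cnn_forward(params, x[bi, , drop = FALSE], config)$logits
  }
  out
}

#' Classify windows with a trained model
#'
#' @param model A `psc_cnn` from [train_detector()].
#' @param windows A `psc_windows` set (standardized internally).
#' @return Numeric vector of event probabilities.
#' @export
predict_windows <- function(model, windows) {
  w <- if (inherits(windows, "psc_windows")) windows$windows else windows
  if (ncol(w) != model$config$window_len)
    stopf("window length mismatch: %d vs model %d", ncol(w), model$config$window_len)
  sigmoid(predict_logits(model$params, standardize_windows(w), model$config))
}

#' Evaluate a trained classifier on labeled windows
#'
#' @param model A `psc_cnn`.
#' @param windows A labeled `psc_windows` set.
#' @return List with `auc`, `accuracy`, and `roc` (data.frame of fpr/tpr,
#'   monotone non-decreasing).
#' @export
evaluate_detector <- function(model, windows) {
  if (length(unique(windows$labels)) < 2L)
    stopf("AUC undefined: windows contain a single class")
  p <- predict_windows(model, windows)
  r <- pROC::roc(response = windows$labels, predictor = p, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  roc_df <- data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  list(auc = as.numeric(pROC::auc(r)),
       accuracy = mean((p > 0.5) == (windows$labels > 0.5)),
       roc = roc_df)
}

#' Sliding-inference detector configuration
#'
#' @param stride Window stride in samples; `NULL` = window_len / 10.
#' @param probability_threshold Event probability threshold in (0, 1].
#' @param min_event_separation Minimum separation between events, ms.
#' @param smooth_probability Centered moving-average width (window
#'   positions) applied to the probability trace; 1 disables.
#' @param min_window_range Degenerate-window guard: windows whose raw
#'   peak-to-peak excursion is below this (pA) are assigned probability 0.
#'   Such windows cannot contain a countable event (the field's floor is
#'   5 pA), and after per-window standardization their rescaled noise is
#'   out of distribution for the classifier. The default of 2 pA is well
#'   below the event floor yet above the residual excursion of event tails.
#' @param min_logit_prominence Required topographic prominence of a
#'   candidate maximum of the classifier score, in logit units. One event
#'   keeps the score high across many overlapping windows, so its score
#'   profile carries shallow wiggles; distinct events are separated by deep
#'   score dips. The default of 4 (the score must dip by ~4 logit units,
#'   e.g. 0.98 to 0.5) suppresses duplicate maxima without merging
#'   resolvable neighbors.
#' @inheritParams mad_config
#' @return An `ml_detect_config` list.
#' @export
ml_detect_config <- function(stride = NULL, probability_threshold = 0.5,
                             min_event_separation = 2, smooth_probability = 1,
                             min_window_range = 2, min_logit_prominence = 4,
                             baseline_window = c(15, 6), refine_window = 5,
                             measure_sigma = 0.25) {
  if (probability_threshold <= 0 || probability_threshold > 1)
    stopf("`probability_threshold` must be in (0, 1]")
  structure(list(stride = stride,
                 probability_threshold = probability_threshold,
                 min_event_separation = min_event_separation,
                 smooth_probability = smooth_probability,
                 min_window_range = min_window_range,
                 min_logit_prominence = min_logit_prominence,
                 baseline_window = baseline_window,
                 refine_window = refine_window,
                 measure_sigma = measure_sigma,
                 min_peak_separation = min_event_separation,
                 min_prominence_frac = 0), class = "ml_detect_config")
}

#' Sliding-window CNN detection
#'
#' Slides the trained classifier along the trace at a fixed stride,
#' producing an event-probability value per window position; contiguous
#' suprathreshold runs are merged into one event each, placed at the
#' directional extremum of the lightly smoothed trace inside the run.
#'
#' @param trace A [trace()] with `mode` set. Its sampling rate must match
#'   the model's training rate (use [resample_for_model()] first otherwise).
#' @param model A `psc_cnn` from [train_detector()].
#' @param config An [ml_detect_config()].
#' @return A [event_table()].
#' @export
detect_ml <- function(trace, model, config = ml_detect_config()) {
  assert_trace(trace)
  wl <- model$config$window_len
  if (length(trace$samples) < wl)
    stopf("trace shorter than the model window (%d samples)", wl)
  if (abs(trace$sampling_rate - model$sampling_rate) > 1e-6)
    stopf("trace sampling rate %g != model rate %g; resample_for_model() first",
          trace$sampling_rate, model$sampling_rate)
  fs <- trace$sampling_rate
  stride <- as.integer(config$stride %||% max(1L, wl %/% 10L))
  n <- length(trace$samples)
  starts <- seq(1L, n - wl + 1L, by = stride)
  # build window matrix in chunks to bound memory
  logits <- numeric(length(starts))
  chunk <- 512L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    ci <- c0:min(length(starts), c0 + chunk - 1L)
    w <- matrix(trace$samples[outer(starts[ci] - 1L, seq_len(wl), "+")],
                nrow = length(ci))
    z <- predict_logits(model$params, standardize_windows(w), model$config)
    # degenerate-window guard: no countable event fits in the excursion
    flat <- (apply(w, 1, max) - apply(w, 1, min)) < config$min_window_range
    z[flat] <- -20
    logits[ci] <- z
  }
  if (config$smooth_probability > 1) {
    k <- rep(1 / config$smooth_probability, config$smooth_probability)
    sm <- stats::filter(logits, k, sides = 2)
    logits <- ifelse(is.na(sm), logits, as.numeric(sm))
  }
  centers <- starts + wl %/% 2L
  # local maxima of the classifier score, greedily thinned by separation in
  # descending score order: raising the threshold then only removes
  # candidates, so the detected-event count is monotone in the threshold
  sep_pos <- max(1L, as.integer(round(
    config$min_event_separation / 1000 * fs / stride)))
  pk <- find_peaks(logits, min_height = stats::qlogis(config$probability_threshold),
                   min_sep = sep_pos, min_prom = config$min_logit_prominence)
  cand <- integer()
  if (length(pk)) {
    pol <- trace_polarity(trace)
    xs <- gaussian_smooth_num(trace$samples, config$measure_sigma / 1000 * fs)
    # the pooled classifier score is shift-tolerant, so the scoring maximum
    # may sit well off the event peak: search the whole window span
    half <- wl %/% 2L
    cand <- vapply(pk, function(i) {
      a <- max(1L, centers[i] - half); b <- min(n, centers[i] + half)
      as.integer(a + which.max(pol * xs[a:b]) - 1L)
    }, integer(1))
  }
  out <- finish_events(trace, trace$samples, cand, config, "MLD")
  attr(out, "n_windows") <- length(starts)
  out
}

#' Resample a trace to a model's sampling rate
#'
#' Polyphase rational-ratio resampling; duration is preserved to within one
#' sample period.
#'
#' @param trace A [trace()].
#' @param target_rate Target sampling rate, Hz.
#' @return A resampled [trace()].
#' @export
resample_for_model <- function(trace, target_rate) {
  assert_trace(trace)
  assert_scalar_num(target_rate, "target_rate", 0, strict = TRUE)
  fs <- trace$sampling_rate
  if (abs(fs - target_rate) < 1e-9) return(trace)
  g <- gcd_int(round(target_rate), round(fs))
  p <- round(target_rate) / g; q <- round(fs) / g
  y <- signal::resample(trace$samples, p, q)
  n_target <- round(length(trace$samples) * target_rate / fs)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  trace(y, target_rate, mode = trace$mode,
        recording_id = trace$meta$recording_id,
        source = paste0(trace$meta$source, ":resampled"))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' @export
print.psc_cnn <- function(x, ...) {
  cat(sprintf("<psc_cnn> window %d samples @ %g Hz, blocks [%s], kernel %d\n",
              x$config$window_len, x$sampling_rate,
              paste(x$config$channels, collapse = "/"), x$config$kernel))
  invisible(x)
}
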