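# Shared fixtures. Everything is generated in code at test time; heavier
# objects (trained classifiers) are built once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a noise-free trace with n isolated events of fixed amplitude
isolated_event_trace <- function(n_events = 10, amplitude = 50, gap = 0.15,
                                 mode = "sIPSC", fs = 20000,
                                 kinetics = NULL) {
  kinetics <- kinetics %||% pscbench:::default_kinetics(mode)
  k <- make_kernel(kinetics, fs)
  ipk <- which.max(abs(k))
  dur <- 0.5 + n_events * gap
  x <- numeric(round(dur * fs))
  peaks <- numeric(n_events)
  for (i in seq_len(n_events)) {
    onset <- round((0.2 + (i - 1) * gap) * fs)
    idx <- onset:(onset + length(k) - 1)
    x[idx] <- x[idx] + amplitude * k
    peaks[i] <- (onset + ipk - 2) / fs
  }
  list(trace = trace(x, fs, mode = mode, recording_id = "isolated"),
       truth = event_table(peak_time = peaks,
                           amplitude = rep(amplitude, n_events),
                           detector = "ground_truth",
                           recording_id = "isolated"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small window classifier for ML unit tests: short windows, thin net,
# trained on two 30 s simulated recordings
small_test_model <- function() {
  memoize("small_model", function() {
    sims <- lapply(1:2, function(i)
      simulate_trace(synthetic_spec(duration = 30, rate = 2, mode = "sIPSC",
                                    seed = 100 + i)))
    win <- extract_training_windows(sims, window_len = 600, seed = 3)
    train_detector(win, model_config(channels = c(8, 16), batch_size = 64,
                                     max_epochs = 40, patience = 8, seed = 5))
  })
}

# full-size classifier trained under the benchmark study conditions; used
# by the CNN-pipeline and detector-ordering acceptance checks
benchmark_model <- function() {
  memoize("benchmark_model", function() {
    win <- benchmark_training_windows()
    train_detector(win, model_config(max_epochs = 25, patience = 4, seed = 11))
  })
}

# >= 2000 windows at event:noise ratio 1.0 from recordings spanning the
# generator's noise range (median SNR >= 5 throughout)
benchmark_training_windows <- function() {
  memoize("benchmark_windows", function() {
    noises <- list(noise_spec(white_sd = 3),
                   noise_spec(white_sd = 1.5, hum = list(freq = 60, amplitude = 1)),
                   noise_spec(white_sd = 0.75))
    sims <- lapply(seq_along(noises), function(i)
      simulate_trace(synthetic_spec(duration = 180, rate = 2, mode = "sIPSC",
                                    noise = noises[[i]], seed = 200 + i,
                                    recording_id = sprintf("train_%d", i))))
    extract_training_windows(sims, window_len = 600, event_noise_ratio = 1,
                             seed = 7)
  })
}

# the benchmark-conditions sIPSC recording used for detector recovery checks
benchmark_recording <- function() {
  memoize("benchmark_recording", function() {
    simulate_trace(synthetic_spec(duration = 180, sampling_rate = 20000,
                                  rate = 2, mode = "sIPSC",
                                  amplitude_median = 25,
                                  amplitude_sigma_ln = 0.5,
                                  noise = noise_spec(white_sd = 3),
                                  seed = 1, recording_id = "benchmark"))
  })
}

# artifact-rich test set: step and spike artifacts on top of white noise
artifact_rich_set <- function(n = 4, duration = 45) {
  memoize("artifact_set", function() {
    lapply(seq_len(n), function(i) {
      simulate_trace(synthetic_spec(
        duration = duration, rate = 2, mode = "sIPSC", seed = 400 + i,
        recording_id = sprintf("artifact_%d", i),
        noise = noise_spec(white_sd = 3,
                           artifacts = list(
                             list(kind = "step", rate = 0.2, magnitude = 15),
                             list(kind = "spike", rate = 0.5, magnitude = 40)))))
    })
  })
}
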