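test_that("kernel peak lands at the analytic extremum of the biexponential", {
  fs <- 20000
  kin <- event_kinetics(0.5, 5, polarity = 1)
  k <- make_kernel(kin, fs)
  # t* = tr*td/(td-tr) * log(td/tr)
  t_star <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)   # ms
  expect_equal(t_star, 1.279, tolerance = 1e-3)
  expect_lte(abs((which.max(k) - 1) / fs * 1000 - t_star), 1000 / fs)
  expect_equal(max(k), 1)

  kneg <- make_kernel(event_kinetics(0.5, 5, polarity = -1), fs)
  expect_equal(min(kneg), -1)
  expect_lte(max(kneg), 0)
})

test_that("slow-decay limit approaches the saturating exponential 1 - exp(-t/tau_r)", {
  fs <- 20000
  k <- make_kernel(event_kinetics(0.5, 5000, polarity = 1), fs)
  t_ms <- (seq_along(k) - 1) / fs * 1000
  first10 <- t_ms <= 10
  expect_equal(k[first10], (1 - exp(-t_ms[first10] / 0.5)), tolerance = 5e-3)
})

test_that("kinetics validation rejects rise >= decay", {
  expect_error(event_kinetics(5, 5), "tau_rise")
  expect_error(make_kernel(event_kinetics(1, 12, 1), 20000, n_decay = 2), "n_decay")
})

test_that("event counts follow the Poisson law of the arrival process", {
  # count statistics do not depend on the sampling rate, so keep traces cheap
  counts <- vapply(1:200, function(s) {
    sp <- synthetic_spec(duration = 180, sampling_rate = 1000, rate = 2,
                         noise = noise_spec(white_sd = 0), seed = s)
    nrow(simulate_trace(sp)$truth)
  }, numeric(1))
  lambda <- 2 * 180
  se <- sqrt(lambda / 200)
  # refractory thinning removes a small, bounded fraction (~rate * 2 ms)
  thin <- lambda * 2 * 0.002
  expect_lt(abs(mean(counts) - (lambda - thin)), 3 * se + thin)
})

test_that("isolated noise-free events reproduce their amplitude and peak time", {
  sp <- synthetic_spec(duration = 20, rate = 0.3, mode = "sIPSC",
                       amplitude_median = 50, amplitude_sigma_ln = 1e-9,
                       noise = noise_spec(white_sd = 0), seed = 1)
  sim <- simulate_trace(sp)
  expect_gte(nrow(sim$truth), 1)
  expect_equal(max(sim$trace$samples), 50, tolerance = 0.01)
  i_max <- which.max(sim$trace$samples)
  expect_lte(min(abs(sim$truth$peak_time - (i_max - 1) / 20000)), 1 / 20000)
})

test_that("simulation is a pure function of the spec and seeds decorrelate", {
  sp <- synthetic_spec(duration = 5, rate = 3, seed = 9)
  a <- simulate_trace(sp); b <- simulate_trace(sp)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
  sp2 <- synthetic_spec(duration = 5, rate = 3, seed = 10)
  c_ <- simulate_trace(sp2)
  expect_false(isTRUE(all.equal(a$truth$peak_time, c_$truth$peak_time)))
})

test_that("trace decomposes exactly into event sum plus noise", {
  sp <- synthetic_spec(duration = 10, rate = 4, seed = 21,
                       noise = noise_spec(white_sd = 2, drift_sd = 0.002,
                                          hum = list(freq = 60, amplitude = 1)))
  sim <- simulate_trace(sp)
  expect_identical(sim$trace$samples,
                   sim$components$events + sim$components$noise)
})

test_that("ground-truth amplitudes re-measure within 5% on sparse noise-free traces", {
  sp <- synthetic_spec(duration = 60, rate = 0.5, mode = "sIPSC",
                       noise = noise_spec(white_sd = 0), seed = 33)
  sim <- simulate_trace(sp)
  gaps <- diff(c(0, sim$truth$peak_time))
  sparse <- which(gaps > 5 * 0.012 & c(gaps[-1], Inf) > 5 * 0.012)
  noise_free <- trace(sim$components$events, 20000, mode = "sIPSC")
  amp <- measure_amplitude(noise_free, sim$truth$peak_time[sparse])
  expect_true(all(abs(amp - sim$truth$amplitude[sparse]) /
                    sim$truth$amplitude[sparse] < 0.05))
})

test_that("noise library components match their specs", {
  lib <- make_noise_library(list(noise_spec(white_sd = 3),
                                 noise_spec(white_sd = 0,
                                            hum = list(freq = 60, amplitude = 5)),
                                 noise_spec(white_sd = 0)),
                            duration = 120, sampling_rate = 2000, seed = 4)
  expect_equal(sd(lib[[1]]$samples), 3, tolerance = 0.02)
  # FFT oracle: spectral peak of the hum trace sits in the 60 Hz bin
  x <- lib[[2]]$samples
  spec <- Mod(stats::fft(x))[2:(length(x) / 2)]
  f_axis <- (2:(length(x) / 2) - 1) * 2000 / length(x)
  expect_equal(f_axis[which.max(spec)], 60, tolerance = 0.02)
  expect_identical(lib[[3]]$samples, rep(0, 240000))
})

test_that("training windows honor ratio, centering and exclusion rules", {
  sims <- lapply(1:2, function(i)
    simulate_trace(synthetic_spec(duration = 20, rate = 1.5, seed = 50 + i)))
  win <- extract_training_windows(sims, window_len = 400,
                                  event_noise_ratio = 1, jitter = 0, seed = 6)
  expect_equal(sum(win$labels == 1), sum(win$labels == 0))
  expect_equal(win$event_noise_ratio, 1, tolerance = 0.02)
  # jitter 0: every event window has its ground-truth peak at the center
  half <- 400 %/% 2
  fs <- 20000
  ev_idx <- which(win$labels == 1)
  all_peaks <- unlist(lapply(sims, function(s) round(s$truth$peak_time * fs) + 1))
  all_traces <- lapply(sims, function(s) s$trace$samples)
  hits <- vapply(ev_idx[1:min(10, length(ev_idx))], function(i) {
    w <- win$windows[i, ]
    center_val <- w[half]
    any(vapply(seq_along(all_traces), function(ti)
      any(abs(all_traces[[ti]][all_peaks] - center_val) < 1e-12), logical(1)))
  }, logical(1))
  expect_true(all(hits))
  # a dense trace cannot satisfy a noise-heavy ratio with long windows
  dense <- simulate_trace(synthetic_spec(duration = 10, rate = 20, seed = 99))
  expect_error(extract_training_windows(list(dense), window_len = 4000,
                                        event_noise_ratio = 0.01, seed = 1),
               "insufficient")
})

test_that("windows with two nearby peaks are excluded from the event class", {
  fs <- 20000
  fake <- isolated_event_trace(n_events = 2, gap = 0.005, amplitude = 40)
  # two peaks 5 ms apart and a 400-sample (20 ms) window: always conflicting
  expect_error(extract_training_windows(list(fake), window_len = 400,
                                        event_noise_ratio = 10, seed = 1),
               "no usable event windows")
})
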