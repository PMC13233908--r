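tol3 <- match_config(tolerance = 3)

test_that("all three detectors fully recover isolated noise-free events", {
  fix <- isolated_event_trace(n_events = 10, amplitude = 50, gap = 0.15)
  for (detect in list(function(tr) detect_mad(tr),
                      function(tr) detect_btd(tr, btd_config(preview_window = c(0, 1))),
                      function(tr) detect_ttd(tr))) {
    ev <- detect(fix$trace)
    expect_equal(nrow(ev), 10)
    sc <- score_detection(fix$truth, ev, tol3)
    expect_equal(sc$precision, 1)
    expect_equal(sc$recall, 1)
    expect_true(all(abs(ev$amplitude - 50) / 50 < 0.05))
  }
})

test_that("constant traces and absurd thresholds yield empty event tables", {
  flat <- trace(rep(3, 40000), 20000, mode = "sIPSC")
  expect_equal(nrow(detect_mad(flat)), 0)
  # constant trace: preview SD is 0, so the threshold degenerates onto the
  # baseline itself; the lone edge candidate is skipped (with a warning)
  expect_warning(ev_flat <- detect_btd(flat, btd_config(preview_window = c(0, 1))),
                 "baseline window")
  expect_equal(nrow(ev_flat), 0)
  fix <- isolated_event_trace(5, 50)
  huge <- btd_config(preview_window = c(0, 1), threshold_multiplier = 1e9)
  expect_equal(nrow(detect_btd(fix$trace, huge)), 0)
  expect_error(detect_mad(trace(rnorm(40000), 20000)), "mode")
  expect_error(detect_mad(trace(rnorm(1000), 20000, mode = "sIPSC")), "short")
})

test_that("MAD false-positive rate on pure white noise stays below 0.2 events/s", {
  set.seed(77)
  tr <- trace(rnorm(20000 * 60, sd = 3), 20000, mode = "sIPSC")
  ev <- detect_mad(tr)
  expect_lt(nrow(ev) / 60, 0.2)
})

test_that("polarity symmetry: flipped trace with flipped mode detects identically", {
  sim <- simulate_trace(synthetic_spec(duration = 20, rate = 2, mode = "sIPSC",
                                       seed = 13))
  flipped <- trace(-sim$trace$samples, 20000, mode = "sEPSC",
                   recording_id = sim$trace$meta$recording_id)
  cfg <- mad_config(k_sepsc = 3.6)  # same multiplier both directions
  a <- detect_mad(sim$trace, cfg)
  b <- detect_mad(flipped, cfg)
  expect_equal(a$peak_time, b$peak_time)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
})

test_that("segmented thresholds recover events under strong baseline drift", {
  sp <- synthetic_spec(duration = 60, rate = 2, mode = "sIPSC", seed = 17,
                       noise = noise_spec(white_sd = 3))
  sim <- simulate_trace(sp)
  drift <- seq(0, 60, length.out = length(sim$trace$samples))  # 60 pA ramp
  drifted <- trace(sim$trace$samples + drift, 20000, mode = "sIPSC",
                   recording_id = "drifted")
  plain <- detect_btd(drifted, btd_config(preview_window = c(0, 5)))
  segmented <- detect_btd(drifted, btd_config(preview_window = c(0, 5),
                                              segment_length = 10))
  late <- sim$truth[sim$truth$peak_time > 30, ]
  tp_late <- function(ev) match_events(late, ev, tol3)$tp
  expect_gte(tp_late(segmented), tp_late(plain))
  expect_gt(tp_late(segmented), 0.8 * nrow(late))
})

test_that("templates built from identical events match the kernel shape", {
  fix <- isolated_event_trace(n_events = 6, amplitude = 50, gap = 0.2)
  cfg <- ttd_config(n_templates = 1)
  tpl <- build_templates(fix$trace, cfg)
  expect_length(tpl, 1)
  k <- make_kernel(event_kinetics(1, 12, 1), 20000)
  geo <- pscbench:::ttd_geometry(cfg, 20000)
  k_aligned <- c(rep(0, geo$pre - which.max(k) + 1), k)[1:geo$len]
  rms <- sqrt(mean((tpl[[1]] - k_aligned)^2))
  expect_lt(rms, 0.02)
})

test_that("template construction fails without suprathreshold seeds and separates shapes", {
  flat <- trace(rnorm(40000, sd = 1), 20000, mode = "sIPSC")
  expect_error(build_templates(flat), "seed")
  # two distinct kinetic populations -> two distinct templates
  fs <- 20000
  fast <- make_kernel(event_kinetics(0.5, 4, 1), fs)
  slow <- make_kernel(event_kinetics(2, 30, 1), fs)
  x <- numeric(fs * 6)
  for (i in 0:4) {
    o1 <- round((0.3 + i) * fs); x[o1:(o1 + length(fast) - 1)] <-
      x[o1:(o1 + length(fast) - 1)] + 40 * fast
    o2 <- round((0.8 + i) * fs); x[o2:(o2 + length(slow) - 1)] <-
      x[o2:(o2 + length(slow) - 1)] + 80 * slow
  }
  tr <- trace(x, fs, mode = "sIPSC")
  tpl <- build_templates(tr, ttd_config(n_templates = 2))
  expect_length(tpl, 2)
  expect_lt(cor(tpl[[1]], tpl[[2]]), 0.99)
})

test_that("template screening rejects square artifacts but keeps true events", {
  fs <- 20000
  sim <- simulate_trace(synthetic_spec(duration = 30, rate = 1.5,
                                       mode = "sIPSC", seed = 23,
                                       noise = noise_spec(white_sd = 2)))
  x <- sim$trace$samples
  step_times <- c(5.11, 13.37, 21.73)
  for (t0 in step_times) {   # 40 pA sustained square steps, 100 ms long
    i <- round(t0 * fs); x[i:(i + 0.1 * fs)] <- x[i:(i + 0.1 * fs)] + 40
  }
  tr <- trace(x, fs, mode = "sIPSC", recording_id = "steps")
  ev <- detect_ttd(tr, ttd_config(), build_templates(sim$trace, ttd_config()))
  # no false positive on a step plateau (true events may coincide by chance)
  m <- match_events(sim$truth, ev, tol3)
  fp_times <- ev$peak_time[m$unmatched_detected]
  on_step <- vapply(fp_times, function(p)
    any(p - step_times > -0.005 & p - step_times < 0.105), logical(1))
  expect_equal(sum(on_step), 0)
  sc <- score_detection(sim$truth, ev, tol3)
  expect_gt(sc$recall, 0.7)
})

test_that("an event identical to the template scores correlation 1 and the screen can be disabled", {
  fix <- isolated_event_trace(n_events = 6, amplitude = 50, gap = 0.2)
  tpl <- build_templates(fix$trace, ttd_config(n_templates = 1))
  ev <- detect_ttd(fix$trace, ttd_config(n_templates = 1), tpl)
  expect_true(all(ev$score > 0.999))
  # correlation cutoff 0 and screens off reduce to the plain threshold candidate set
  sim <- simulate_trace(synthetic_spec(duration = 20, rate = 2, mode = "sIPSC",
                                       seed = 31))
  ns <- estimate_noise_stats(sim$trace)
  open_cfg <- ttd_config(correlation_cutoff = -1, min_rise_time = 0,
                         min_amplitude = 0)
  ttd_open <- detect_ttd(sim$trace, open_cfg, tpl)
  btd_same <- detect_btd(sim$trace,
                         btd_config(preview_window = c(0, 5),
                                    fixed_threshold = 5 * ns$sd,
                                    min_amplitude = 0))
  # compare away from the edges the template geometry excludes
  interior <- function(t) t > 0.1 & t < 19.9
  expect_equal(ttd_open$peak_time[interior(ttd_open$peak_time)],
               btd_same$peak_time[interior(btd_same$peak_time)],
               tolerance = 1e-9)
})

test_that("raising thresholds never increases detected-event counts", {
  sim <- simulate_trace(synthetic_spec(duration = 20, rate = 3, mode = "sIPSC",
                                       seed = 41))
  n_mad <- vapply(c(2, 3.6, 6), function(k)
    nrow(detect_mad(sim$trace, mad_config(k_sipsc = k))), numeric(1))
  expect_true(all(diff(n_mad) <= 0))
  n_btd <- vapply(c(2, 4, 8), function(m)
    nrow(detect_btd(sim$trace, btd_config(preview_window = c(0, 5),
                                          threshold_multiplier = m))),
    numeric(1))
  expect_true(all(diff(n_btd) <= 0))
  tpl <- build_templates(sim$trace, ttd_config())
  n_ttd <- vapply(c(0.3, 0.6, 0.9), function(cc)
    nrow(detect_ttd(sim$trace, ttd_config(correlation_cutoff = cc), tpl)),
    numeric(1))
  expect_true(all(diff(n_ttd) <= 0))
})

test_that("detection is deterministic for a fixed trace and config", {
  sim <- simulate_trace(synthetic_spec(duration = 15, rate = 2, mode = "sEPSC",
                                       seed = 55))
  expect_identical(detect_mad(sim$trace), detect_mad(sim$trace))
  cfg <- btd_config(preview_window = c(0, 5))
  expect_identical(detect_btd(sim$trace, cfg), detect_btd(sim$trace, cfg))
})
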