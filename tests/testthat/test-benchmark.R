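ms <- function(x) x / 1000

test_that("greedy matching reproduces the worked example and the optimal oracle", {
  ref <- event_table(peak_time = ms(c(11, 29)), amplitude = c(10, 20))
  det <- event_table(peak_time = ms(c(10, 20, 30)), amplitude = c(9, 5, 21))
  m <- match_events(ref, det, match_config(tolerance = 3))
  expect_equal(m$tp, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 0)
  expect_equal(sort(m$pairs$det_index), c(1, 3))
  opt <- oracle_optimal_match(ref, det, match_config(tolerance = 3))
  expect_equal(m$tp, opt$tp)
  pr <- precision_recall(m)
  expect_equal(unname(pr["precision"]), 2 / 3)
  expect_equal(unname(pr["recall"]), 1)
})

test_that("degenerate matchings follow the conventions", {
  ref <- event_table(peak_time = c(1, 2, 3), amplitude = c(1, 2, 3))
  none <- event_table()
  m <- match_events(ref, none)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 3))
  pr <- precision_recall(m)
  expect_equal(unname(pr), c(1, 0))   # nothing detected: precision 1, recall 0
  m2 <- match_events(none, none)
  expect_equal(unname(precision_recall(m2)), c(1, 1))
  m3 <- match_events(ref, ref)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(3, 0, 0))
})

test_that("matching counts are conserved and symmetric on random instances", {
  set.seed(5)
  for (i in 1:200) {
    nr <- sample(0:8, 1); nd <- sample(0:8, 1)
    ref <- event_table(peak_time = sort(runif(nr, 0, 0.08)),
                       amplitude = runif(nr, 5, 50))
    det <- event_table(peak_time = sort(runif(nd, 0, 0.08)),
                       amplitude = runif(nd, 5, 50))
    m <- match_events(ref, det)
    expect_equal(m$tp + m$fn, nr)
    expect_equal(m$tp + m$fp, nd)
    sw <- match_events(det, ref)
    expect_equal(sw$tp, m$tp)
    expect_equal(sw$fp, m$fn)
    expect_equal(sw$fn, m$fp)
    opt <- oracle_optimal_match(ref, det)
    expect_lte(m$tp, opt$tp)
  }
})

test_that("f_beta follows the closed form, its identities and limits", {
  expect_equal(f_beta(0.8, 0.5, 0.3), 1.09 * 0.4 / (0.09 * 0.8 + 0.5),
               tolerance = 1e-12)
  expect_equal(f_beta(0.8, 0.5, 0.3), 0.7622, tolerance = 1e-4)
  for (x in seq(0, 1, by = 0.25)) expect_equal(f_beta(x, x), x)
  expect_equal(f_beta(0.9, 0), 0)
  expect_equal(f_beta(0, 0), 0)
  expect_error(f_beta(0.5, 0.5, beta = 0), "beta")
  # strictly increasing in each argument when both positive
  expect_gt(f_beta(0.6, 0.5), f_beta(0.5, 0.5))
  expect_gt(f_beta(0.5, 0.6), f_beta(0.5, 0.5))
})

test_that("amplitude-binned scores bin Fps by detected and FNs by reference amplitude", {
  cfg <- match_config(tolerance = 3, bin_edges = c(0, 10, 20, 30))
  ref <- event_table(peak_time = c(0.1, 0.2, 0.3), amplitude = c(5, 15, 25))
  det <- event_table(peak_time = c(0.1, 0.2, 0.5), amplitude = c(6, 14, 35))
  m <- match_events(ref, det, cfg)
  b <- binned_f_beta(m, cfg)
  expect_equal(b$tp, c(1, 1, 0, 0))
  expect_equal(b$fn, c(0, 0, 1, 0))
  expect_equal(b$fp, c(0, 0, 0, 1))      # 35 pA FP in the overflow bin
  expect_equal(sum(b$tp), m$tp)
  expect_equal(sum(b$fp), m$fp)
  expect_equal(sum(b$fn), m$fn)
  # single-bin tables reduce to the overall score
  cfg1 <- match_config(tolerance = 3, bin_edges = c(0, 100))
  b1 <- binned_f_beta(m, cfg1)
  pr <- precision_recall(m)
  expect_equal(b1$f_beta[1], unname(f_beta(pr["precision"], pr["recall"], 0.3)))
  # an FN-only bin scores 0; empty bins are NA
  expect_equal(b$f_beta[3], 0)
  fully_empty <- binned_f_beta(match_events(event_table(), event_table(), cfg), cfg)
  expect_true(all(is.na(fully_empty$f_beta)))
})

test_that("aggregation reports mean and SEM across recordings", {
  r1 <- score_detection(event_table(peak_time = c(1, 2), amplitude = c(1, 1)),
                        event_table(peak_time = c(1, 2), amplitude = c(1, 1)))
  make_rep <- function(f) { r1$f_beta <- f; r1$precision <- f; r1$recall <- f; r1 }
  agg <- aggregate_scores(list(make_rep(0.6), make_rep(0.8)))
  fb <- agg[agg$metric == "f_beta", ]
  expect_equal(fb$mean, 0.7)
  expect_equal(fb$sem, 0.1)
  expect_equal(fb$n, 2)
  single <- aggregate_scores(list(make_rep(0.5)))
  expect_true(all(is.na(single$sem)))
  same <- aggregate_scores(list(make_rep(0.4), make_rep(0.4)))
  expect_equal(same[same$metric == "f_beta", "sem"], 0)
})

test_that("the exhaustive oracle enforces its size cap", {
  big <- event_table(peak_time = seq(0.01, 1.3, by = 0.1),
                     amplitude = rep(1, 13))
  expect_error(oracle_optimal_match(big, big), "12")
})
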