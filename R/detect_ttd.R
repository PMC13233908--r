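# Template/threshold detection (TTD): events are seeded with a flat
# amplitude threshold, averaged into a small template bank, and candidate
# deflections are screened by similarity to the bank.

#' Template/threshold detector configuration
#'
#' Defaults mirror the described template workflow: seed events collected
#' with a flat +30 pA (sIPSC) / -20 pA (sEPSC) threshold, three templates
#' per recording, candidate detection at 5 x SD beyond the noise band, a
#' correlation cutoff of 0.6, exclusion of events with rise times below
#' 0.03 ms (printed as "30 mcs"; below one sample at 20 kHz, so inert
#' unless raised), and a 5 pA minimum amplitude.
#'
#' @param seed_threshold Flat seed threshold magnitude, pA; `NULL` picks
#'   30 (sIPSC) or 20 (sEPSC) by trace mode.
#' @param n_templates Number of templates (seed events are grouped by peak
#'   amplitude and averaged per group).
#' @param detection_multiplier Candidate threshold, x SD of the noise band.
#' @param correlation_cutoff Minimum Pearson correlation with the best
#'   template (`score_method = "correlation"`).
#' @param score_method `"correlation"` or `"clements_bekkers"` (scaled
#'   template fit; detection criterion = fitted scale / SE of the fit).
#' @param cb_cutoff Detection-criterion cutoff for the Clements-Bekkers
#'   scorer.
#' @param min_rise_time Exclude events with 10-90% rise time below this, ms.
#' @param min_amplitude Minimum event amplitude, pA.
#' @param template_length Template length, ms (should cover >= 5 decay time
#'   constants); `pre` ms of baseline precede the aligned peak.
#' @param pre Pre-peak portion of the template, ms.
#' @param smoothing_sigma Gaussian sigma, ms, applied before analysis.
#' @inheritParams mad_config
#' @return A `ttd_config` list.
#' @export
ttd_config <- function(seed_threshold = NULL, n_templates = 3,
                       detection_multiplier = 5, correlation_cutoff = 0.6,
                       score_method = c("correlation", "clements_bekkers"),
                       cb_cutoff = 4, min_rise_time = 0.03, min_amplitude = 5,
                       template_length = 60, pre = 5, smoothing_sigma = 0.25,
                       min_peak_separation = 2, baseline_window = c(15, 6),
                       refine_window = 5, measure_sigma = 0.25) {
  score_method <- match.arg(score_method)
  if (correlation_cutoff > 1) stopf("`correlation_cutoff` must be <= 1")
  structure(list(seed_threshold = seed_threshold, n_templates = n_templates,
                 detection_multiplier = detection_multiplier,
                 correlation_cutoff = correlation_cutoff,
                 score_method = score_method, cb_cutoff = cb_cutoff,
                 min_rise_time = min_rise_time, min_amplitude = min_amplitude,
                 template_length = template_length, pre = pre,
                 smoothing_sigma = smoothing_sigma,
                 min_peak_separation = min_peak_separation,
                 baseline_window = baseline_window,
                 refine_window = refine_window, measure_sigma = measure_sigma,
                 min_prominence_frac = 0), class = "ttd_config")
}

ttd_seed_threshold <- function(trace, config) {
  config$seed_threshold %||% if (trace$mode == "sIPSC") 30 else 20
}

# template sample geometry: pre samples before the aligned peak
ttd_geometry <- function(config, fs) {
  pre <- round(config$pre / 1000 * fs)
  len <- round(config$template_length / 1000 * fs)
  list(pre = pre, post = len - pre - 1L, len = len)
}

#' Build a template bank from a recording
#'
#' Seed events are local extrema of the smoothed trace beyond the flat seed
#' threshold. Seeds are grouped by peak amplitude into `n_templates` groups
#' (k-means on amplitude with deterministic quantile starts) and each
#' group's peak-aligned snippets are averaged and scaled to unit peak.
#'
#' @param trace A [trace()] with `mode` set.
#' @param config A [ttd_config()].
#' @return List of unit-peak numeric templates (signed by event polarity),
#'   with the sample index of the aligned peak in attribute `"peak"`.
#' @export
build_templates <- function(trace, config = ttd_config()) {
  assert_trace(trace, min_duration = 1)
  pol <- trace_polarity(trace)
  fs <- trace$sampling_rate
  x <- gaussian_smooth(trace, config$smoothing_sigma)$samples
  med <- stats::median(x)
  thr <- med + pol * ttd_seed_threshold(trace, config)
  geo <- ttd_geometry(config, fs)
  pk <- crossing_peaks(pol * x, pol * thr)
  pk <- pk[pk - geo$pre >= 1 & pk + geo$post <= length(x)]
  if (length(pk) < config$n_templates)
    stopf(paste0("only %d seed event(s) beyond the flat %g pA seed threshold; ",
                 "need >= %d — lower `seed_threshold`"),
          length(pk), ttd_seed_threshold(trace, config), config$n_templates)
  amp <- pol * (x[pk] - med)
  groups <- if (config$n_templates == 1L || length(unique(amp)) < config$n_templates) {
    rep(1L, length(pk))
  } else {
    centers <- matrix(stats::quantile(amp, probs = seq(0.1, 0.9,
                      length.out = config$n_templates)), ncol = 1)
    stats::kmeans(matrix(amp, ncol = 1), centers = centers)$cluster
  }
  lapply(seq_len(max(groups)), function(g) {
    snips <- vapply(pk[groups == g],
                    function(p) x[(p - geo$pre):(p + geo$post)] - med,
                    numeric(geo$pre + geo$post + 1L))
    tpl <- rowMeans(snips)
    tpl <- tpl / max(abs(tpl))
    if (sign(tpl[geo$pre + 1L]) != pol) tpl <- tpl * sign(tpl[geo$pre + 1L]) * pol
    attr(tpl, "peak") <- geo$pre + 1L
    tpl
  })
}

# Clements-Bekkers detection criterion for one window vs a template:
# least-squares fit data = scale * template + offset, criterion = scale / SE
cb_criterion <- function(w, tpl) {
  n <- length(tpl)
  st <- sum(tpl); sw <- sum(w)
  stt <- sum(tpl^2); stw <- sum(tpl * w)
  denom <- stt - st^2 / n
  if (denom <= 0) return(0)
  scale <- (stw - st * sw / n) / denom
  offset <- (sw - scale * st) / n
  sse <- sum((w - scale * tpl - offset)^2)
  se <- sqrt(max(sse, 1e-12) / (n - 2) / denom)
  scale / se
}

#' Template/threshold detection (TTD)
#'
#' Candidate peaks are local extrema of the smoothed trace beyond
#' `detection_multiplier` x SD of the noise band (100 Hz high-pass of the
#' raw trace). Each candidate window is scored against the template bank
#' (max over templates) by Pearson correlation (default) or the
#' Clements-Bekkers scaled-template criterion; survivors are further
#' screened on rise time and minimum amplitude.
#'
#' @param trace A [trace()] with `mode` set.
#' @param config A [ttd_config()].
#' @param templates Optional template bank from [build_templates()]; built
#'   from the trace itself if omitted.
#' @return A [event_table()] with the per-event best template score in
#'   column `score`.
#' @export
detect_ttd <- function(trace, config = ttd_config(), templates = NULL) {
  assert_trace(trace, min_duration = 1)
  pol <- trace_polarity(trace)
  fs <- trace$sampling_rate
  if (is.null(templates)) templates <- build_templates(trace, config)
  if (!length(templates)) stopf("empty template bank")
  x <- gaussian_smooth(trace, config$smoothing_sigma)$samples
  med <- stats::median(x)
  ns <- estimate_noise_stats(trace)
  thr <- med + pol * config$detection_multiplier * ns$sd
  geo <- ttd_geometry(config, fs)
  cand <- crossing_peaks(pol * x, pol * thr)
  cand <- cand[cand - geo$pre >= 1 & cand + geo$post <= length(x)]
  if (length(cand)) {
    score <- vapply(cand, function(p) {
      w <- x[(p - geo$pre):(p + geo$post)]
      max(vapply(templates, function(tpl) {
        if (config$score_method == "correlation") {
          if (stats::sd(w) == 0 || stats::sd(tpl) == 0) 0 else stats::cor(w, tpl)
        } else cb_criterion(w, tpl)
      }, numeric(1)))
    }, numeric(1))
    cutoff <- if (config$score_method == "correlation")
      config$correlation_cutoff else config$cb_cutoff
    keep <- score >= cutoff
    cand <- cand[keep]; score <- score[keep]
  } else score <- numeric()
  out <- finish_events(trace, x, cand, config, "TTD")
  # re-attach scores by nearest candidate (refinement can move peaks slightly)
  if (nrow(out)) {
    ci <- round(out$peak_time * fs) + 1L
    out$score <- vapply(ci, function(i) {
      if (!length(cand)) return(NA_real_)
      score[which.min(abs(cand - i))]
    }, numeric(1))
    keep <- rep(TRUE, nrow(out))
    if (config$min_amplitude > 0)
      keep <- keep & (is.na(out$amplitude) | out$amplitude >= config$min_amplitude)
    if (config$min_rise_time > 0)
      keep <- keep & (is.na(out$rise_time) | out$rise_time >= config$min_rise_time)
    out <- out[keep, ]
    class(out) <- c("psc_events", "data.frame")
  }
  attr(out, "threshold") <- thr
  out
}
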