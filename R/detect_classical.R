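# Classical detectors: robust MAD thresholding on band-passed traces,
# baseline-threshold detection (BTD), and template/threshold detection (TTD).

#' MAD detector configuration
#'
#' Defaults follow the published robust-threshold pipeline: a 3rd-order
#' 0.05-50 Hz band-pass for detection, a 3rd-order 100 Hz high-pass for the
#' noise band, inclusion thresholds of median(filtered) + 3.6 x MAD(noise)
#' for sIPSCs and median(filtered) - 2.5 x MAD(noise) for sEPSCs, and a
#' pre-peak baseline window 15 to 6 ms before the peak.
#'
#' @param band `c(low, high)` detection band-pass corners, Hz.
#' @param order Butterworth order.
#' @param noise_highpass Noise-band high-pass corner, Hz.
#' @param k_sipsc,k_sepsc Threshold multipliers on the noise-band MAD.
#' @param baseline_window `c(start, end)` pre-peak baseline window, ms.
#' @param min_peak_separation Minimum separation between events, ms.
#' @param mad_variant `"mean"` (mean absolute deviation, the default) or
#'   `"median"` (median absolute deviation).
#' @param min_prominence_frac Required peak prominence in the filtered trace
#'   as a fraction of (threshold - median); suppresses duplicate maxima on a
#'   single event.
#' @param refine_window Half-width, ms, of the raw-trace window in which the
#'   reported peak time is relocated to the directional extremum of the
#'   lightly smoothed unfiltered trace (the band-pass is zero-phase, but its
#'   smoothing still biases peak positions of asymmetric events).
#' @param measure_sigma Gaussian sigma, ms, for raw-trace point measurements.
#' @param zero_phase Apply filters forward-backward (default).
#' @return A `mad_config` list.
#' @export
mad_config <- function(band = c(0.05, 50), order = 3, noise_highpass = 100,
                       k_sipsc = 3.6, k_sepsc = 2.5,
                       baseline_window = c(15, 6), min_peak_separation = 2,
                       mad_variant = c("mean", "median"),
                       min_prominence_frac = 0.5, refine_window = 5,
                       measure_sigma = 0.25, zero_phase = TRUE) {
  mad_variant <- match.arg(mad_variant)
  if (k_sipsc <= 0 || k_sepsc <= 0) stopf("threshold multipliers must be > 0")
  if (baseline_window[1] <= baseline_window[2] || baseline_window[2] <= 0)
    stopf("baseline window must satisfy start > end > 0 (ms before peak)")
  structure(list(band = band, order = order, noise_highpass = noise_highpass,
                 k_sipsc = k_sipsc, k_sepsc = k_sepsc,
                 baseline_window = baseline_window,
                 min_peak_separation = min_peak_separation,
                 mad_variant = mad_variant,
                 min_prominence_frac = min_prominence_frac,
                 refine_window = refine_window, measure_sigma = measure_sigma,
                 zero_phase = zero_phase), class = "mad_config")
}

# shared finisher: candidate peak indices on a processed trace -> event table.
# Peak times are refined to the directional extremum of the lightly smoothed
# raw trace near each candidate; amplitudes are measured on both the
# processed ("filtered") and smoothed raw traces; edge events are dropped.
finish_events <- function(trace, filt_samples, cand_idx, config, detector) {
  fs <- trace$sampling_rate
  pol <- trace_polarity(trace)
  n <- length(trace$samples)
  if (!length(cand_idx)) {
    return(event_table(detector = detector, recording_id = trace$meta$recording_id))
  }
  xs <- gaussian_smooth_num(trace$samples, config$measure_sigma / 1000 * fs)
  rw <- round(config$refine_window / 1000 * fs)
  refined <- vapply(cand_idx, function(i) {
    a <- max(1L, i - rw); b <- min(n, i + rw)
    seg <- pol * xs[a:b]
    as.integer(a + which.max(seg) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # collapse refinements that landed within the minimum separation
  if (length(refined) > 1) {
    min_sep <- round(config$min_peak_separation / 1000 * fs)
    keep <- logical(length(refined)); keep[1] <- TRUE; last <- refined[1]
    for (i in seq_along(refined)[-1]) {
      if (refined[i] - last >= min_sep) { keep[i] <- TRUE; last <- refined[i] }
    }
    refined <- refined[keep]
  }
  b0 <- round(config$baseline_window[1] / 1000 * fs)
  b1 <- round(config$baseline_window[2] / 1000 * fs)
  ok <- refined - b0 >= 1L & refined <= n
  n_skip <- sum(!ok)
  if (n_skip) warning(sprintf("%d event(s) within the baseline window of the trace start; skipped", n_skip))
  refined <- refined[ok]
  amp_raw <- numeric(length(refined)); amp_fil <- numeric(length(refined))
  for (i in seq_along(refined)) {
    p <- refined[i]
    sr <- xs[(p - b0):(p - b1)]; sf <- filt_samples[(p - b0):(p - b1)]
    if (pol > 0) {
      amp_raw[i] <- xs[p] - min(sr); amp_fil[i] <- filt_samples[p] - min(sf)
    } else {
      amp_raw[i] <- max(sr) - xs[p]; amp_fil[i] <- max(sf) - filt_samples[p]
    }
  }
  pt <- (refined - 1L) / fs
  rt <- measure_rise_time(trace, pt, baseline_window = config$baseline_window,
                          smooth_sigma = config$measure_sigma)
  event_table(peak_time = pt, amplitude = pmax(amp_raw, 0),
              rise_time = rt, detector = detector,
              recording_id = trace$meta$recording_id,
              amplitude_filtered = pmax(amp_fil, 0))
}

#' Robust MAD threshold detection
#'
#' Pipeline: (1) band-pass the trace (0.05-50 Hz, 3rd order, zero-phase);
#' (2) estimate the noise band from a 100 Hz high-pass of the raw trace and
#' take its MAD; (3) set the inclusion threshold at the median of the
#' filtered trace plus `k_sipsc` x MAD (sIPSC, upward) or minus `k_sepsc` x
#' MAD (sEPSC, downward); (4) find local extrema of the filtered trace in
#' the event direction (minimum separation and prominence rules suppress
#' duplicate maxima); (5) keep extrema beyond the threshold; (6) report
#' peak times and amplitudes from the lightly smoothed unfiltered trace
#' (filtered-trace amplitudes are retained in `amplitude_filtered`).
#'
#' @param trace A [trace()] with `mode` set; needs >= 1 s of data.
#' @param config A [mad_config()].
#' @return A [event_table()] sorted by peak time.
#' @export
detect_mad <- function(trace, config = mad_config()) {
  assert_trace(trace, min_duration = 1)
  pol <- trace_polarity(trace)
  x0 <- trace$samples - stats::median(trace$samples)
  work <- trace; work$samples <- x0
  filt <- butterworth_filter(work, order = config$order,
                             low_cut = config$band[1], high_cut = config$band[2],
                             zero_phase = config$zero_phase)
  ns <- estimate_noise_stats(work, highpass = config$noise_highpass,
                             order = config$order)
  mad <- if (config$mad_variant == "mean") ns$mad_mean else ns$mad_median
  med <- stats::median(filt$samples)
  k <- if (pol > 0) config$k_sipsc else config$k_sepsc
  thr <- med + pol * k * mad
  fs <- trace$sampling_rate
  dir_sig <- pol * filt$samples
  cand <- find_peaks(dir_sig, min_height = pol * thr,
                     min_sep = round(config$min_peak_separation / 1000 * fs),
                     min_prom = config$min_prominence_frac * (pol * thr - pol * med),
                     wlen = round(0.1 * fs))
  out <- finish_events(trace, filt$samples, cand, config, "MAD")
  attr(out, "threshold") <- thr
  attr(out, "noise_stats") <- ns
  out
}

#' Baseline-threshold detector configuration
#'
#' Mirrors plain threshold detection: the noise band is previewed in an
#' initial stretch of the recording, the threshold is the trace median plus
#' (in the event direction) a multiple of the preview SD, and a standard
#' Gaussian filter is applied before analysis. Optional fixed-length
#' segmentation recomputes median and threshold per segment for drifting
#' recordings.
#'
#' @param preview_window `c(start, end)`, s, of the noise-preview stretch.
#' @param threshold_multiplier Multiplier on the preview SD (default 3).
#' @param smoothing_sigma Gaussian sigma, ms, applied before analysis.
#' @param segment_length Segment length in s for per-segment thresholds, or
#'   `NULL` to use a single threshold for the whole recording.
#' @param min_amplitude Discard events smaller than this, pA.
#' @param min_peak_separation Minimum separation between events, ms.
#' @param fixed_threshold Absolute threshold level in pA (overrides the
#'   SD-based rule when given; used for deliberately naive baselines).
#' @inheritParams mad_config
#' @return A `btd_config` list.
#' @export
btd_config <- function(preview_window = c(0, 10), threshold_multiplier = 3,
                       smoothing_sigma = 0.25, segment_length = NULL,
                       min_amplitude = 5, min_peak_separation = 2,
                       baseline_window = c(15, 6), refine_window = 5,
                       measure_sigma = 0.25, fixed_threshold = NULL) {
  if (threshold_multiplier <= 0) stopf("`threshold_multiplier` must be > 0")
  structure(list(preview_window = preview_window,
                 threshold_multiplier = threshold_multiplier,
                 smoothing_sigma = smoothing_sigma,
                 segment_length = segment_length,
                 min_amplitude = min_amplitude,
                 min_peak_separation = min_peak_separation,
                 baseline_window = baseline_window,
                 refine_window = refine_window, measure_sigma = measure_sigma,
                 fixed_threshold = fixed_threshold,
                 min_prominence_frac = 0), class = "btd_config")
}

#' Baseline-threshold detection (BTD)
#'
#' Gaussian-smooths the trace, estimates the noise SD from the preview
#' window, thresholds at median +/- multiplier x SD in the event direction,
#' and reports suprathreshold local extrema as events. With
#' `segment_length` set, the median and threshold are recomputed per
#' segment, which restores sensitivity under slow baseline drift.
#'
#' @param trace A [trace()] with `mode` set.
#' @param config A [btd_config()].
#' @return A [event_table()].
#' @export
detect_btd <- function(trace, config = btd_config()) {
  assert_trace(trace, min_duration = 1)
  pol <- trace_polarity(trace)
  fs <- trace$sampling_rate
  if (config$preview_window[2] > trace$meta$duration)
    stopf("preview window [%g, %g] s exceeds the trace (%.2f s)",
          config$preview_window[1], config$preview_window[2], trace$meta$duration)
  sm <- gaussian_smooth(trace, config$smoothing_sigma)
  x <- sm$samples
  n <- length(x)
  i0 <- max(1L, floor(config$preview_window[1] * fs) + 1L)
  i1 <- min(n, ceiling(config$preview_window[2] * fs))
  preview_sd <- stats::sd(x[i0:i1])
  seg_len <- if (is.null(config$segment_length)) n else
    max(100L, round(config$segment_length * fs))
  starts <- seq(1L, n, by = seg_len)
  min_sep <- round(config$min_peak_separation / 1000 * fs)
  cand <- integer()
  for (s in starts) {
    e <- min(n, s + seg_len - 1L)
    seg <- x[s:e]
    med <- stats::median(seg)
    thr <- if (!is.null(config$fixed_threshold)) {
      med + pol * config$fixed_threshold
    } else {
      sd_use <- if (is.null(config$segment_length)) preview_sd else stats::sd(seg)
      med + pol * config$threshold_multiplier * sd_use
    }
    pk <- crossing_peaks(pol * seg, pol * thr)
    cand <- c(cand, pk + s - 1L)
  }
  out <- finish_events(trace, x, cand, config, "BTD")
  if (nrow(out) && config$min_amplitude > 0)
    out <- out[is.na(out$amplitude) | out$amplitude >= config$min_amplitude, ]
  class(out) <- c("psc_events", "data.frame")
  attr(out, "preview_sd") <- preview_sd
  out
}
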