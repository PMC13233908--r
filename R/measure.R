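# Point measurements on traces: event amplitude and 10-90% rise time.

#' Measure event amplitude
#'
#' Amplitude is the unsigned difference between the trace value at the peak
#' and the pre-peak baseline, where the baseline is the directional extremum
#' (minimum for upward sIPSC events, maximum for downward sEPSC events) in a
#' window 15 to 6 ms before the peak. Point measurements on an unfiltered
#' trace are dominated by single-sample noise, so by default the trace is
#' lightly Gaussian-smoothed first (`smooth_sigma` ms); pass
#' `smooth_sigma = NULL` for raw point reads.
#'
#' @param trace A [trace()] object with `mode` set (or pass `mode`).
#' @param peak_time Event peak times, s.
#' @param mode Override for the trace mode.
#' @param baseline_window `c(start, end)` of the pre-peak baseline window in
#'   ms before the peak (default `c(15, 6)`).
#' @param smooth_sigma Gaussian smoothing sigma in ms applied before the
#'   point reads, or `NULL` for none.
#' @return Numeric vector of amplitudes (pA, >= 0); `NA` (with a warning
#'   summarising the count) for peaks too close to the trace start.
#' @export
measure_amplitude <- function(trace, peak_time, mode = NULL,
                              baseline_window = c(15, 6),
                              smooth_sigma = 0.25) {
  assert_trace(trace)
  if (!is.null(mode)) trace$mode <- mode
  pol <- trace_polarity(trace)
  fs <- trace$sampling_rate
  x <- if (is.null(smooth_sigma)) trace$samples else
    gaussian_smooth_num(trace$samples, smooth_sigma / 1000 * fs)
  b0 <- round(baseline_window[1] / 1000 * fs)
  b1 <- round(baseline_window[2] / 1000 * fs)
  if (b0 <= b1 || b1 < 0) stopf("baseline window start must exceed end (ms before peak)")
  idx <- round(peak_time * fs) + 1L
  n <- length(x)
  out <- rep(NA_real_, length(idx))
  skipped <- 0L
  for (i in seq_along(idx)) {
    p <- idx[i]
    if (p - b0 < 1L || p > n) { skipped <- skipped + 1L; next }
    base_seg <- x[(p - b0):(p - b1)]
    base <- if (pol > 0) min(base_seg) else max(base_seg)
    out[i] <- abs(x[p] - base)
  }
  if (skipped)
    warning(sprintf("%d event(s) too close to the trace edge; amplitude set NA", skipped))
  out
}

#' Measure 10-90% rise time
#'
#' Finds the last pre-peak crossing of 10% and 90% of the peak-minus-baseline
#' excursion (baseline as in [measure_amplitude()]) and returns their
#' separation, linearly interpolated between samples.
#'
#' @inheritParams measure_amplitude
#' @return Rise times in ms (`NA` where not measurable).
#' @export
measure_rise_time <- function(trace, peak_time, mode = NULL,
                              baseline_window = c(15, 6),
                              smooth_sigma = 0.25) {
  assert_trace(trace)
  if (!is.null(mode)) trace$mode <- mode
  pol <- trace_polarity(trace)
  fs <- trace$sampling_rate
  x <- if (is.null(smooth_sigma)) trace$samples else
    gaussian_smooth_num(trace$samples, smooth_sigma / 1000 * fs)
  x <- pol * x   # work in event-positive orientation
  b0 <- round(baseline_window[1] / 1000 * fs)
  b1 <- round(baseline_window[2] / 1000 * fs)
  idx <- round(peak_time * fs) + 1L
  out <- rep(NA_real_, length(idx))
  for (i in seq_along(idx)) {
    p <- idx[i]
    if (p - b0 < 1L || p > length(x)) next
    base <- min(x[(p - b0):(p - b1)])
    amp <- x[p] - base
    if (amp <= 0) next
    seg <- x[(p - b0):p]
    hi <- base + 0.9 * amp
    lo <- base + 0.1 * amp
    cross <- function(level) {
      below <- which(seg[-length(seg)] < level & seg[-1] >= level)
      if (!length(below)) return(NA_real_)
      j <- max(below)   # last crossing before the peak
      j + (level - seg[j]) / (seg[j + 1] - seg[j])
    }
    t_hi <- cross(hi); t_lo <- cross(lo)
    if (is.na(t_hi) || is.na(t_lo) || t_hi <= t_lo) next
    out[i] <- (t_hi - t_lo) / fs * 1000
  }
  out
}
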