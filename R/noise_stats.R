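#' Robust noise statistics of a recording
#'
#' Estimates the noise band by high-pass filtering the raw trace (3rd-order
#' Butterworth, 100 Hz corner by default) so that synaptic events, whose
#' power is concentrated well below 100 Hz, are largely removed, and then
#' computing robust spread statistics: the mean absolute deviation and the
#' median absolute deviation from the median, together with the SD.
#'
#' @param trace A [trace()] object.
#' @param window Optional `c(start, end)` time range in seconds to restrict
#'   the estimate to; whole trace if omitted. Must cover >= 100 samples.
#' @param highpass High-pass corner in Hz, or `NULL` to skip filtering and
#'   compute the statistics on the raw samples.
#' @param order Butterworth order for the noise-band filter.
#'
#' @return A list of class `noise_stats`: `median`, `sd`, `mad_mean`
#'   (mean |x - median|), `mad_median` (median |x - median|), all in pA.
#'   For Gaussian noise, `mad_median ~= 0.6745 sd` and `mad_mean ~= 0.7979 sd`.
#' @export
estimate_noise_stats <- function(trace, window = NULL, highpass = 100,
                                 order = 3) {
  assert_trace(trace)
  x <- trace$samples
  if (!is.null(highpass)) {
    x <- butterworth_filter(trace, order = order, low_cut = highpass)$samples
  }
  if (!is.null(window)) {
    fs <- trace$sampling_rate
    i0 <- max(1L, floor(window[1] * fs) + 1L)
    i1 <- min(length(x), ceiling(window[2] * fs))
    if (i1 < i0 || (i1 - i0 + 1L) < 100L)
      stopf("noise window must lie inside the trace and cover >= 100 samples")
    x <- x[i0:i1]
  }
  med <- stats::median(x)
  dev <- abs(x - med)
  structure(list(median = med, sd = stats::sd(x),
                 mad_mean = mean(dev), mad_median = stats::median(dev)),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("<noise_stats> median %.3g pA, sd %.3g, mad_mean %.3g, mad_median %.3g\n",
              x$median, x$sd, x$mad_mean, x$mad_median))
  invisible(x)
}
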