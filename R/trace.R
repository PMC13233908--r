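#' Voltage-clamp current trace
#'
#' A `psc_trace` holds a uniformly sampled whole-cell current recording in
#' picoamperes together with its sampling rate and recording mode. The mode
#' records which polarity carries the synaptic signal: spontaneous EPSCs are
#' downward (negative) deflections recorded at about -70 mV, spontaneous
#' IPSCs are upward (positive) deflections recorded at about +10 mV.
#'
#' @param samples Numeric vector of current samples (pA). Must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param mode Recording mode, `"sEPSC"`, `"sIPSC"`, or `NA` if unknown.
#' @param recording_id Identifier used in event tables and reports.
#' @param holding_potential Optional holding potential (mV), metadata only.
#' @param source Provenance string, e.g. a file path or `"synthetic"`.
#'
#' @return An object of class `psc_trace`: a list with elements `samples`,
#'   `sampling_rate`, `mode` and `meta` (recording_id, holding_potential,
#'   source, duration in seconds).
#' @export
#' @examples
#' tr <- trace(rnorm(2000), 20000, mode = "sIPSC")
#' print(tr)
trace <- function(samples, sampling_rate, mode = NA_character_,
                  recording_id = "trace", holding_potential = NA_real_,
                  source = "memory") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stopf("`samples` must be a non-empty numeric vector")
  if (anyNA(samples) || any(!is.finite(samples)))
    stopf("`samples` must be finite (no NA/Inf)")
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  if (!is.na(mode)) mode <- match.arg(mode, c("sEPSC", "sIPSC"))
  structure(list(
    samples = as.numeric(samples),
    sampling_rate = as.numeric(sampling_rate),
    mode = mode,
    meta = list(
      recording_id = as.character(recording_id),
      holding_potential = holding_potential,
      source = source,
      duration = length(samples) / sampling_rate
    )
  ), class = "psc_trace")
}

is_trace <- function(x) inherits(x, "psc_trace")

assert_trace <- function(x, min_duration = 0) {
  if (!is_trace(x)) stopf("expected a `psc_trace` object")
  if (x$meta$duration < min_duration)
    stopf("trace too short: %.3f s, need >= %g s", x$meta$duration, min_duration)
  invisible(x)
}

# signal polarity of the event direction: -1 for sEPSC, +1 for sIPSC
trace_polarity <- function(x) {
  if (is.na(x$mode)) stopf("trace `mode` must be set (sEPSC or sIPSC)")
  if (x$mode == "sIPSC") 1 else -1
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf("<psc_trace> %s: %d samples @ %g Hz (%.2f s), mode %s, source %s\n",
              x$meta$recording_id, length(x$samples), x$sampling_rate,
              x$meta$duration, x$mode, x$meta$source))
  invisible(x)
}

#' @export
length.psc_trace <- function(x) length(x$samples)

#' Event table
#'
#' Construct the canonical per-event table used by all detectors and the
#' benchmarking layer. Rows are ordered by peak time.
#'
#' @param peak_time Event peak times (s), will be sorted.
#' @param amplitude Event amplitudes as positive magnitudes (pA).
#' @param onset_time Optional onset times (s).
#' @param rise_time Optional 10-90% rise times (ms).
#' @param detector Detector label, recycled.
#' @param recording_id Recording identifier, recycled.
#' @param amplitude_filtered Optional amplitudes measured on the filtered
#'   trace (pA); detectors that filter report both.
#'
#' @return A `data.frame` of class `psc_events` with columns `recording_id`,
#'   `detector`, `peak_time`, `onset_time`, `amplitude`, `rise_time`,
#'   `amplitude_filtered`.
#' @export
event_table <- function(peak_time = numeric(), amplitude = numeric(),
                        onset_time = NULL, rise_time = NULL,
                        detector = "unknown", recording_id = "trace",
                        amplitude_filtered = NULL) {
  n <- length(peak_time)
  if (length(amplitude) != n) stopf("`amplitude` must match `peak_time` length")
  if (n && any(amplitude < 0, na.rm = TRUE)) stopf("amplitudes must be >= 0")
  onset_time <- onset_time %||% rep(NA_real_, n)
  rise_time <- rise_time %||% rep(NA_real_, n)
  amplitude_filtered <- amplitude_filtered %||% rep(NA_real_, n)
  ord <- order(peak_time)
  out <- data.frame(
    recording_id = rep_len(as.character(recording_id), n)[ord],
    detector = rep_len(as.character(detector), n)[ord],
    peak_time = as.numeric(peak_time)[ord],
    onset_time = as.numeric(onset_time)[ord],
    amplitude = as.numeric(amplitude)[ord],
    rise_time = as.numeric(rise_time)[ord],
    amplitude_filtered = as.numeric(amplitude_filtered)[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("psc_events", "data.frame")
  out
}

is_event_table <- function(x) inherits(x, "psc_events")

as_event_table <- function(x) {
  if (is_event_table(x)) return(x)
  event_table(peak_time = x$peak_time, amplitude = x$amplitude,
              onset_time = x$onset_time, rise_time = x$rise_time,
              detector = x$detector %||% "unknown",
              recording_id = x$recording_id %||% "trace",
              amplitude_filtered = x$amplitude_filtered)
}

#' @export
print.psc_events <- function(x, ...) {
  cat(sprintf("<psc_events> %d events, detector(s): %s\n", nrow(x),
              paste(unique(x$detector), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
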