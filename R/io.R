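# Trace and event-table I/O.
#
# Canonical on-disk forms:
#   * trace table: CSV with header `time_s,current_pA`, constant time step;
#   * trace HDF5: datasets /trace (pA), /sampling_rate (Hz), /mode (string);
#   * event CSV: header recording_id, detector, peak_time_s, onset_time_s,
#     amplitude_pA, rise_time_ms (plus optional amplitude_filtered_pA).
# Internally times are seconds and currents pA; ms/Hz appear only in configs.

#' Read a current trace from disk
#'
#' @param path File path.
#' @param format One of `"table"` (CSV `time_s,current_pA`), `"hdf5"`
#'   (datasets `/trace`, `/sampling_rate`, `/mode`; requires the `rhdf5`
#'   package), or `"abf"`. Axon Binary Format reading is not bundled; the
#'   `abf` branch signals an unsupported-format error advising conversion to
#'   the table format. Defaults to a guess from the file extension.
#' @param mode Optional recording mode to attach (`"sEPSC"`/`"sIPSC"`).
#' @param recording_id Identifier; defaults to the file name.
#'
#' @return A [trace()] object.
#' @export
read_trace <- function(path, format = c("guess", "table", "hdf5", "abf"),
                       mode = NA_character_, recording_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "table", tsv = "table", h5 = "hdf5",
                     hdf5 = "hdf5", abf = "abf",
                     stopf("cannot guess trace format from extension '.%s'", ext))
  }
  recording_id <- recording_id %||% tools::file_path_sans_ext(basename(path))
  switch(format,
    table = read_trace_table(path, mode, recording_id),
    hdf5 = read_trace_hdf5(path, mode, recording_id),
    abf = stopf(paste0(
      "ABF reading is not bundled with this package; export the recording ",
      "as a two-column time/current table (time_s,current_pA) or HDF5 and ",
      "use format = 'table' or 'hdf5'"))
  )
}

read_trace_table <- function(path, mode, recording_id) {
  d <- utils::read.csv(path, header = TRUE)
  if (ncol(d) < 2L) stopf("trace table needs two columns (time_s, current_pA): %s", path)
  tm <- as.numeric(d[[1]]); cur <- as.numeric(d[[2]])
  if (length(tm) < 2L) stopf("trace table must contain at least 2 samples")
  steps <- diff(tm)
  step <- stats::median(steps)
  if (step <= 0 || any(abs(steps - step) > 1e-6 * max(step, 1e-12) + 1e-12))
    stopf("non-uniform time base in %s: time steps vary", path)
  trace(cur, sampling_rate = 1 / step, mode = mode,
        recording_id = recording_id, source = path)
}

read_trace_hdf5 <- function(path, mode, recording_id) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("HDF5 trace I/O requires the `rhdf5` package")
  cur <- as.numeric(rhdf5::h5read(path, "trace"))
  fs <- as.numeric(rhdf5::h5read(path, "sampling_rate"))
  md <- tryCatch(as.character(rhdf5::h5read(path, "mode")), error = function(e) NA_character_)
  if (is.na(mode) && length(md) == 1L && !is.na(md) && nzchar(md) && md != "NA")
    mode <- md
  trace(cur, sampling_rate = fs, mode = mode,
        recording_id = recording_id, source = path)
}

#' Write a trace to disk
#'
#' @param trace A [trace()] object.
#' @param path Output path.
#' @param format `"table"` (CSV) or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("table", "hdf5")) {
  assert_trace(trace)
  format <- match.arg(format)
  if (format == "table") {
    n <- length(trace$samples)
    d <- data.frame(time_s = num17((seq_len(n) - 1) / trace$sampling_rate),
                    current_pA = num17(trace$samples))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stopf("HDF5 trace I/O requires the `rhdf5` package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(trace$samples, path, "trace")
    rhdf5::h5write(trace$sampling_rate, path, "sampling_rate")
    rhdf5::h5write(as.character(trace$mode), path, "mode")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bit-exactly
num17 <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

event_csv_columns <- c("recording_id", "detector", "peak_time_s",
                       "onset_time_s", "amplitude_pA", "rise_time_ms")

#' Write an event table to CSV
#'
#' Columns: `recording_id, detector, peak_time_s, onset_time_s,
#' amplitude_pA, rise_time_ms, amplitude_filtered_pA`. An empty table
#' produces a header-only file.
#'
#' @param events A [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_table(events)
  d <- data.frame(recording_id = events$recording_id,
                  detector = events$detector,
                  peak_time_s = num17(events$peak_time),
                  onset_time_s = num17(events$onset_time),
                  amplitude_pA = num17(events$amplitude),
                  rise_time_ms = num17(events$rise_time),
                  amplitude_filtered_pA = num17(events$amplitude_filtered))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path Path to a CSV written by [write_events()] (or any CSV with at
#'   least the mandatory columns).
#' @return A [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- tryCatch(utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE),
                error = function(e) stopf("malformed event CSV %s: %s", path, conditionMessage(e)))
  missing_cols <- setdiff(event_csv_columns, names(d))
  if (length(missing_cols))
    stopf("event CSV %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(d$peak_time_s) & !is.finite(as.numeric(d$peak_time_s)))
  if (length(bad)) stopf("event CSV %s: non-numeric peak_time_s at data line %d", path, bad[1])
  event_table(peak_time = as.numeric(d$peak_time_s),
              amplitude = as.numeric(d$amplitude_pA),
              onset_time = as.numeric(d$onset_time_s),
              rise_time = as.numeric(d$rise_time_ms),
              detector = if (nrow(d)) d$detector else "unknown",
              recording_id = if (nrow(d)) d$recording_id else "trace",
              amplitude_filtered = if ("amplitude_filtered_pA" %in% names(d))
                as.numeric(d$amplitude_filtered_pA) else NULL)
}
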