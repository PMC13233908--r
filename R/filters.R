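# Shared filtering primitives.
#
# Butterworth filters are designed as cascaded second-order sections from the
# analytic prototype poles (bilinear transform with frequency prewarping).
# The polynomial transfer-function form returned by signal::butter() loses
# precision catastrophically at very low normalized cutoffs (0.05 Hz on
# 20 kHz data is 5e-6 of Nyquist), while biquad sections remain stable.

# second-order sections for an order-n Butterworth low- or high-pass
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 1) stopf("filter `order` must be >= 1")
  if (fc <= 0 || fc >= fs / 2) stopf("cutoff must lie in (0, Nyquist)")
  K <- 2 * fs
  wc <- K * tan(pi * fc / fs)   # prewarped analog cutoff
  secs <- list()
  if (order %% 2 == 1) {        # real pole at -wc
    if (type == "low") { b <- wc * c(1, 1, 0); a <- c(K + wc, wc - K, 0) }
    else               { b <- K  * c(1, -1, 0); a <- c(K + wc, wc - K, 0) }
    secs[[1]] <- list(b = b / a[1], a = a / a[1])
  }
  for (k in seq_len(order %/% 2)) {
    theta <- pi * (2 * k + order - 1) / (2 * order)  # prototype pole angle
    a1 <- -2 * cos(theta)
    den <- c(K^2 + a1 * wc * K + wc^2, -2 * K^2 + 2 * wc^2,
             K^2 - a1 * wc * K + wc^2)
    num <- if (type == "low") wc^2 * c(1, 2, 1) else K^2 * c(1, -2, 1)
    secs[[length(secs) + 1L]] <- list(b = num / den[1], a = den / den[1])
  }
  secs
}

# single forward pass through an SOS cascade
sos_filter <- function(secs, x) {
  for (s in secs) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# zero-phase (forward-backward) pass with odd-extension padding so that edge
# transients of slow high-pass sections decay inside the pad, not the data
sos_filtfilt <- function(secs, x, pad) {
  n <- length(x)
  pad <- max(0L, min(as.integer(pad), n - 1L))
  if (pad > 0) {
    pre <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    x <- c(pre, x, post)
  }
  y <- sos_filter(secs, x)
  y <- rev(sos_filter(secs, rev(y)))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

# pad long enough for ~5 time constants of the slowest corner frequency
default_pad <- function(fs, f_lowest) as.integer(ceiling(5 * fs / (2 * pi * f_lowest)))

# analytic magnitude response of the filters designed above (single pass,
# ignoring bilinear warping, which is negligible far below Nyquist)
butter_magnitude <- function(f, order, low_cut = NULL, high_cut = NULL) {
  mag <- rep(1, length(f))
  if (!is.null(high_cut)) mag <- mag / sqrt(1 + (f / high_cut)^(2 * order))
  if (!is.null(low_cut)) mag <- mag / sqrt(1 + (low_cut / f)^(2 * order))
  mag
}

#' Butterworth filtering of a trace
#'
#' Applies an order-`order` Butterworth low-pass, high-pass, or band-pass
#' (cascade of high- and low-pass sections) filter. By default the filter is
#' applied forward and backward (zero-phase), so isolated event peaks are not
#' shifted in time; the effective magnitude response is then the square of
#' the single-pass response.
#'
#' @param trace A [trace()] object.
#' @param order Filter order (per section for the band-pass cascade).
#' @param low_cut High-pass corner frequency in Hz, or `NULL` for none.
#' @param high_cut Low-pass corner frequency in Hz, or `NULL` for none.
#' @param zero_phase Apply forward-backward (default) rather than single pass.
#'
#' @return A filtered `psc_trace` of the same length.
#' @export
#' @examples
#' tr <- trace(rnorm(20000), 20000)
#' f <- butterworth_filter(tr, 3, low_cut = 0.05, high_cut = 50)
butterworth_filter <- function(trace, order = 3, low_cut = NULL,
                               high_cut = NULL, zero_phase = TRUE) {
  assert_trace(trace)
  fs <- trace$sampling_rate
  if (is.null(low_cut) && is.null(high_cut))
    stopf("at least one of `low_cut`, `high_cut` must be given")
  for (fc in c(low_cut, high_cut)) {
    if (fc <= 0 || fc >= fs / 2)
      stopf("cutoff %g Hz outside (0, Nyquist = %g Hz)", fc, fs / 2)
  }
  if (!is.null(low_cut) && !is.null(high_cut) && low_cut >= high_cut)
    stopf("`low_cut` must be below `high_cut`")
  x <- trace$samples
  cascades <- list()
  if (!is.null(low_cut)) cascades <- c(cascades, list(list(
    secs = butter_sos(order, low_cut, fs, "high"), pad = default_pad(fs, low_cut))))
  if (!is.null(high_cut)) cascades <- c(cascades, list(list(
    secs = butter_sos(order, high_cut, fs, "low"), pad = default_pad(fs, high_cut))))
  for (cs in cascades) {
    x <- if (zero_phase) sos_filtfilt(cs$secs, x, cs$pad) else sos_filter(cs$secs, x)
  }
  out <- trace
  out$samples <- x
  out
}

#' Gaussian smoothing of a trace
#'
#' Smooths with a symmetric, unit-gain (DC gain 1) discrete Gaussian kernel;
#' edges are handled by reflection so constant traces are preserved exactly.
#' This is the "standard Gaussian filter" applied before threshold-style
#' detection and before point measurements on the raw trace.
#'
#' @param trace A [trace()] object.
#' @param sigma Kernel standard deviation in milliseconds (> 0).
#'
#' @return A smoothed `psc_trace` of the same length.
#' @export
gaussian_smooth <- function(trace, sigma = 0.25) {
  assert_trace(trace)
  assert_scalar_num(sigma, "sigma", 0, strict = TRUE)
  sig <- sigma / 1000 * trace$sampling_rate   # samples
  out <- trace
  out$samples <- gaussian_smooth_num(trace$samples, sig)
  out
}

gaussian_smooth_num <- function(x, sigma_samples) {
  r <- max(1L, as.integer(ceiling(4 * sigma_samples)))
  k <- stats::dnorm(-r:r, sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  r <- min(r, n - 1L)
  k <- k[(length(k) + 1L) %/% 2 + (-r:r)]
  k <- k / sum(k)
  if (r == 0L) return(x)
  xe <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])  # reflect edges
  as.numeric(stats::filter(xe, k, sides = 2))[(r + 1):(r + n)]
}

# discrete Gaussian kernel (exported for tests of normalization)
gaussian_kernel <- function(sigma_samples) {
  r <- max(1L, as.integer(ceiling(4 * sigma_samples)))
  k <- stats::dnorm(-r:r, sd = sigma_samples)
  k / sum(k)
}

# Threshold-crossing candidates: one index (the directional extremum) per
# contiguous suprathreshold run of `dir_sig` (already oriented so events are
# positive). Mirrors the re-arm behaviour of threshold detectors: a new
# event cannot trigger until the signal falls back below threshold.
crossing_peaks <- function(dir_sig, thr) {
  hot <- dir_sig >= thr
  if (!any(hot)) return(integer())
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  idx <- which(r$values)
  vapply(idx, function(i) {
    a <- begins[i]; b <- ends[i]
    as.integer(a + which.max(dir_sig[a:b]) - 1L)
  }, integer(1))
}

# Local-maxima finder used by all classical detectors.
# Returns indices of local maxima of `x` with height >= min_height, pairwise
# separation >= min_sep samples, and topographic prominence >= min_prom
# (prominence evaluated inside a +/- wlen window). Higher peaks win ties.
find_peaks <- function(x, min_height = -Inf, min_sep = 1L, min_prom = 0,
                       wlen = length(x)) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx <- idx[x[idx] >= min_height]
  if (!length(idx)) return(integer())
  o <- idx[order(x[idx], decreasing = TRUE)]
  acc <- integer()
  for (i in o) {
    if (length(acc) && min(abs(acc - i)) < min_sep) next
    if (min_prom > 0) {
      l <- max(1L, i - wlen); r <- min(n, i + wlen)
      li <- i; while (li > l && x[li] <= x[i]) li <- li - 1L
      ri <- i; while (ri < r && x[ri] <= x[i]) ri <- ri + 1L
      prom <- x[i] - max(min(x[li:i]), min(x[i:ri]))
      if (prom < min_prom) next
    }
    acc <- c(acc, i)
  }
  sort(acc)
}
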