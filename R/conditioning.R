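#' Rectify and smooth a raw trace (integrated waveform)
#'
#' Builds the "integrated" waveform of a nerve recording: the absolute value
#' of the signal smoothed by a centered moving average with a 0.05-s window
#' by default. Edges use shrinking windows (the mean over the available
#' samples), so the output has the same length and time base as the input
#' and no spurious zeros at the record boundaries.
#'
#' @param x A raw [trace()].
#' @param window Moving-average window length (s); must cover at least one
#'   sample.
#' @return An integrated [trace()] (kind `"integrated"`).
#' @details The window covers `round(window * fs)` samples; for even counts
#'   the extra sample is taken on the right. `integrate_trace` is
#'   1-homogeneous (`integrate_trace(a * x) = |a| * integrate_trace(x)`) and
#'   its output lies in `[0, max|x|]`.
#' @export
integrate_trace <- function(x, window = 0.05) {
  stopifnot(inherits(x, "rb_trace"))
  if (x$kind != "raw") stop("`x` must be a raw trace")
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("`window` must be a single positive number")
  L <- round(window * x$fs)
  if (L < 1) stop("`window` is shorter than one sample period")
  a <- abs(x$samples)
  n <- length(a)
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  cs <- c(0, cumsum(a))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  y <- trace(out, x$fs, channel = x$channel, t0 = x$t0, kind = "integrated")
  attr(y, "window") <- window
  y
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase), as used
#' to condition raw nerve signals before rectification. The synthetic
#' generator emits signals already in band, so this stage is optional there.
#'
#' @param x A raw [trace()].
#' @param lo,hi Corner frequencies (Hz), `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A filtered raw [trace()].
#' @export
bandpass_trace <- function(x, lo, hi, order = 4) {
  stopifnot(inherits(x, "rb_trace"))
  if (x$kind != "raw") stop("`x` must be a raw trace")
  nyq <- x$fs / 2
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo)
    stop("need 0 < lo < hi")
  if (hi >= nyq)
    stop(sprintf("`hi` = %g Hz violates the Nyquist bound fs/2 = %g Hz", hi, nyq))
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  trace(signal::filtfilt(bf, x$samples), x$fs, channel = x$channel,
        t0 = x$t0, kind = "raw")
}

#' Detect R waves in an ECG trace
#'
#' Threshold-crossing local maxima with a refractory period. The threshold is
#' `k` times a robust SD (median absolute deviation) of the signal; when
#' several candidate peaks fall within one refractory interval the largest
#' is kept.
#'
#' @param x A raw ECG [trace()] of duration > 2 s.
#' @param k Threshold in robust SDs (default 4).
#' @param refractory Minimum spacing between accepted peaks (s, default 0.15).
#' @return An [event_series()] of R-wave times; empty for a flat signal.
#' @export
detect_r_peaks <- function(x, k = 4, refractory = 0.15) {
  stopifnot(inherits(x, "rb_trace"))
  if (trace_duration(x) <= 2) stop("ECG trace must be longer than 2 s")
  v <- x$samples
  thr <- k * stats::mad(v)
  n <- length(v)
  if (n < 3) return(event_series(numeric(0), "R"))
  core <- 2:(n - 1L)
  is_peak <- v[core] > thr & v[core] >= v[core - 1L] & v[core] > v[core + 1L]
  cand <- core[is_peak]
  if (!length(cand)) return(event_series(numeric(0), "R"))
  # greedy by amplitude, enforcing the refractory period
  cand <- cand[order(v[cand], decreasing = TRUE)]
  ref_n <- refractory * x$fs
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= ref_n)) kept <- c(kept, i)
  kept <- sort(kept)
  event_series(x$t0 + (kept - 1L) / x$fs, "R")
}

# internal: mean of `values` in half-open bins [k*step, (k+1)*step) covering
# t_range; returns bin centers and means, NA for empty bins (gaps, not zeros)
bin_mean <- function(times, values, step, t_range = NULL) {
  if (is.null(t_range)) t_range <- range(times)
  k0 <- floor(t_range[1] / step)
  k1 <- ceiling(t_range[2] / step) - 1L
  if (k1 < k0) k1 <- k0
  ks <- k0:k1
  idx <- floor(times / step)
  val <- vapply(ks, function(k) {
    sel <- idx == k
    if (!any(sel)) NA_real_ else mean(values[sel])
  }, numeric(1))
  data.frame(time = (ks + 0.5) * step, value = val)
}

#' Heart rate time course from R-wave times
#'
#' Instantaneous HR is `60 / RR` (beats/min), assigned to the midpoint of
#' each R-R interval, then averaged within bins of the common analysis grid.
#'
#' @param rpeaks An [event_series()] of R-wave times.
#' @param step Grid step (s, default 10).
#' @param t_range Optional two-element time range (s) the grid should cover;
#'   defaults to the span of the interval midpoints.
#' @return A [metric_timecourse()] with metric `"HR"`; empty (with a
#'   warning) when fewer than two R waves are available.
#' @export
heart_rate <- function(rpeaks, step = 10, t_range = NULL) {
  stopifnot(inherits(rpeaks, "rb_events"))
  if (length(rpeaks$times) < 2L) {
    warning("fewer than 2 R waves; returning an empty heart-rate time course")
    return(metric_timecourse(numeric(0), numeric(0), "HR", step))
  }
  rr <- diff(rpeaks$times)
  mid <- rpeaks$times[-length(rpeaks$times)] + rr / 2
  b <- bin_mean(mid, 60 / rr, step, t_range)
  metric_timecourse(b$time, b$value, "HR", step)
}
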