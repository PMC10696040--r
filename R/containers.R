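#' Construct a single-channel trace
#'
#' A `rb_trace` holds one uniformly sampled channel of a recording session:
#' either a raw signal (nerve activity, ECG, perfusion pressure) or an
#' integrated (rectified + smoothed) waveform.
#'
#' @param samples Numeric vector of signal values (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param channel Channel label, e.g. `"PNA"`, `"VNA"`, `"ECG"`, `"PP"`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param kind Either `"raw"` or `"integrated"`.
#' @return An object of class `rb_trace`.
#' @export
trace <- function(samples, fs, channel = "PNA", t0 = 0, kind = c("raw", "integrated")) {
  kind <- match.arg(kind)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  fs <- as.numeric(fs)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite")
  if (kind == "integrated" && any(samples < 0))
    stop("an integrated trace must be non-negative everywhere")
  structure(
    list(channel = as.character(channel), t0 = as.numeric(t0), fs = fs,
         samples = samples, kind = kind),
    class = "rb_trace"
  )
}

#' @export
print.rb_trace <- function(x, ...) {
  cat(sprintf("<rb_trace> channel=%s kind=%s fs=%g Hz n=%d (%.1f s from t0=%g)\n",
              x$channel, x$kind, x$fs, length(x$samples),
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Time axis of a trace
#' @param x An `rb_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "rb_trace"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Duration of a trace in seconds
#' @param x An `rb_trace`.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "rb_trace"))
  length(x$samples) / x$fs
}

#' Construct an event series
#'
#' Holds strictly increasing event times: R-wave times, burst-onset trigger
#' times, injection markers.
#'
#' @param times Numeric vector of event times (s), strictly increasing.
#' @param label Series label.
#' @return An object of class `rb_events`.
#' @export
event_series <- function(times, label = "events") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("event times must not contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  structure(list(label = as.character(label), times = times), class = "rb_events")
}

#' @export
print.rb_events <- function(x, ...) {
  cat(sprintf("<rb_events> %s: %d events", x$label, length(x$times)))
  if (length(x$times)) cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Construct a metric time course
#'
#' A metric sampled on the common analysis grid (10-s steps by default):
#' respiratory frequency, phase durations, burst amplitudes, heart rate.
#' Values at bins with no data are gaps (`NA`), never zeros.
#'
#' @param time Bin-center times (s), strictly increasing.
#' @param value Metric values in native units; `NA` marks an empty bin.
#' @param metric Metric label, one of `"amp_PNA"`, `"amp_postinsp_VNA"`,
#'   `"f"`, `"Ti"`, `"Te"`, `"ratio"`, `"HR"` (other labels allowed).
#' @param step Grid step in seconds.
#' @return A `data.frame` of class `rb_timecourse` with columns `time`,
#'   `value` and (after [percent_of_baseline()]) `percent`.
#' @export
metric_timecourse <- function(time, value, metric, step = NA_real_) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value)) stop("`time` and `value` lengths differ")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing")
  out <- data.frame(time = time, value = value)
  attr(out, "metric") <- as.character(metric)
  attr(out, "step") <- step
  class(out) <- c("rb_timecourse", "data.frame")
  out
}

#' @export
print.rb_timecourse <- function(x, ...) {
  cat(sprintf("<rb_timecourse> metric=%s, %d bins, %d gaps%s\n",
              attr(x, "metric"), nrow(x), sum(is.na(x$value)),
              if (!is.null(x$percent)) ", percent-normalized" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# internal: half-open interval membership [lo, hi)
`%inco%` <- function(x, bounds) x >= bounds[1] & x < bounds[2]
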