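#' Burst-triggered average waveforms over sliding windows
#'
#' For each sliding window (20 s wide, advanced in 10-s steps by default),
#' collects the triggers (phrenic burst onsets) falling inside it, extracts
#' the segment `lag` around each trigger from every integrated channel, and
#' averages pointwise. Windows containing no usable trigger produce a gap
#' (they are absent from the result), never a zero waveform. Triggers whose
#' lag segment would leave the record are skipped and counted.
#'
#' @param traces Named list of integrated [trace()] objects sharing `fs` and
#'   `t0` (e.g. `list(PNA = ..., VNA = ...)`).
#' @param triggers An [event_series()] of trigger times, or a numeric
#'   vector.
#' @param window Window length (s, default 20).
#' @param step Window advance (s, default 10).
#' @param lag Two-element lag range (s) around each trigger; should span at
#'   least one full respiratory cycle.
#' @param t_range Optional range of window start times; defaults to the
#'   trace span.
#' @return A list of `rb_trigavg` objects, each a list with
#'   `window_start`, `window_end`, `lag_axis`, `mean_traces` (named list of
#'   numeric vectors), `n_triggers` and `n_skipped`.
#' @export
triggered_average <- function(traces, triggers, window = 20, step = 10,
                              lag = c(-1, 5), t_range = NULL) {
  if (inherits(traces, "rb_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  for (tr in traces) {
    stopifnot(inherits(tr, "rb_trace"))
    if (tr$kind != "integrated") stop("all traces must be integrated")
  }
  fs <- traces[[1]]$fs; t0 <- traces[[1]]$t0
  n <- length(traces[[1]]$samples)
  for (tr in traces)
    if (tr$fs != fs || abs(tr$t0 - t0) > 1 / fs || length(tr$samples) != n)
      stop("all traces must share sampling rate, start time and length")
  tt <- if (inherits(triggers, "rb_events")) triggers$times else as.numeric(triggers)
  if (length(lag) != 2L || lag[2] <= lag[1]) stop("`lag` must be increasing")
  il <- round(lag[1] * fs):round(lag[2] * fs)
  lag_axis <- il / fs
  if (is.null(t_range)) t_range <- c(t0, t0 + n / fs)
  starts <- seq(t_range[1], t_range[2] - window, by = step)
  if (!length(starts)) stop("no complete window fits in `t_range`")

  out <- list()
  for (ws in starts) {
    in_win <- tt[tt %inco% c(ws, ws + window)]
    if (!length(in_win)) next
    i0 <- round((in_win - t0) * fs) + 1L
    ok <- i0 + il[1] >= 1L & i0 + il[length(il)] <= n
    n_skip <- sum(!ok)
    i0 <- i0[ok]
    if (!length(i0)) next
    mean_traces <- lapply(traces, function(tr) {
      segs <- vapply(i0, function(i) tr$samples[i + il],
                     numeric(length(il)))
      rowMeans(matrix(segs, nrow = length(il)))
    })
    out[[length(out) + 1L]] <- structure(
      list(window_start = ws, window_end = ws + window, lag_axis = lag_axis,
           mean_traces = mean_traces, n_triggers = length(i0),
           n_skipped = n_skip),
      class = "rb_trigavg")
  }
  out
}

#' @export
print.rb_trigavg <- function(x, ...) {
  cat(sprintf("<rb_trigavg> window [%.1f, %.1f) s, %d triggers, channels: %s\n",
              x$window_start, x$window_end, x$n_triggers,
              paste(names(x$mean_traces), collapse = ", ")))
  invisible(x)
}

# internal: mean of an averaged waveform over a half-open lag interval
lag_mean <- function(avg, channel, interval) {
  sel <- avg$lag_axis %inco% interval
  if (!any(sel)) stop("lag interval outside the averaged lag axis")
  mean(avg$mean_traces[[channel]][sel])
}

#' Burst amplitude from an averaged waveform
#'
#' Amplitude = maximum of the averaged trace within the burst lag interval,
#' minus the pre-trigger baseline (the mean over `baseline_lag`, a span
#' ending just before the trigger so it is not contaminated by the burst).
#'
#' @param avg An `rb_trigavg` object.
#' @param channel Channel name present in `avg`.
#' @param burst_lag Two-element lag interval (s) containing the burst,
#'   half-open.
#' @param baseline_lag Two-element pre-trigger lag span (s), default
#'   `c(-0.5, -0.1)`.
#' @return Amplitude (a.u.).
#' @export
amplitude_from_average <- function(avg, channel = "PNA",
                                   burst_lag = c(0, 1.5),
                                   baseline_lag = c(-0.5, -0.1)) {
  stopifnot(inherits(avg, "rb_trigavg"))
  if (!channel %in% names(avg$mean_traces))
    stop(sprintf("channel '%s' not present in the average", channel))
  sel <- avg$lag_axis %inco% burst_lag
  if (!any(sel)) stop("burst lag interval is empty on the lag axis")
  base <- lag_mean(avg, channel, baseline_lag)
  max(avg$mean_traces[[channel]][sel]) - base
}

#' Post-inspiratory VNA amplitude from an averaged waveform
#'
#' The post-inspiratory vagal component lives just after the phrenic
#' offset: amplitude = maximum of the averaged \eqn{\int}VNA in the lag
#' interval `(pna_offset_lag, pna_offset_lag + w_pi]`, minus the
#' pre-trigger VNA baseline.
#'
#' @param avg An `rb_trigavg` object with a VNA channel.
#' @param pna_offset_lag Lag of the phrenic offset relative to the trigger
#'   (s); with onset triggers this is the (median) inspiratory duration.
#' @param w_pi Width of the post-inspiratory search interval (s);
#'   typically half the median expiratory duration.
#' @param channel VNA channel name.
#' @inheritParams amplitude_from_average
#' @return Amplitude (a.u.).
#' @export
postinsp_vna_amplitude <- function(avg, pna_offset_lag, w_pi,
                                   channel = "VNA",
                                   baseline_lag = c(-0.5, -0.1)) {
  stopifnot(inherits(avg, "rb_trigavg"))
  if (!channel %in% names(avg$mean_traces))
    stop(sprintf("channel '%s' not present in the average", channel))
  hi <- pna_offset_lag + w_pi
  if (hi > max(avg$lag_axis))
    stop("post-inspiratory interval extends beyond the lag axis")
  sel <- avg$lag_axis > pna_offset_lag & avg$lag_axis <= hi
  if (!any(sel)) stop("post-inspiratory interval is empty on the lag axis")
  base <- lag_mean(avg, channel, baseline_lag)
  max(avg$mean_traces[[channel]][sel]) - base
}

#' Amplitude time course from a set of triggered averages
#'
#' Measures one amplitude per sliding window and places it at the window
#' center on the common grid; windows absent from `avgs` (no triggers)
#' appear as gaps.
#'
#' @param avgs List of `rb_trigavg` objects from [triggered_average()].
#' @param channel Channel to measure.
#' @param kind `"burst"` (uses [amplitude_from_average()]) or `"postinsp"`
#'   (uses [postinsp_vna_amplitude()]).
#' @param metric Metric label for the resulting time course.
#' @param ... Passed to the amplitude function.
#' @return A [metric_timecourse()].
#' @export
amplitude_timecourse <- function(avgs, channel = "PNA",
                                 kind = c("burst", "postinsp"),
                                 metric = if (kind == "burst") "amp_PNA"
                                          else "amp_postinsp_VNA", ...) {
  kind <- match.arg(kind)
  if (!length(avgs)) stop("`avgs` is empty")
  centers <- vapply(avgs, function(a) (a$window_start + a$window_end) / 2,
                    numeric(1))
  vals <- vapply(avgs, function(a)
    if (kind == "burst") amplitude_from_average(a, channel, ...)
    else postinsp_vna_amplitude(a, channel = channel, ...), numeric(1))
  step <- if (length(avgs) > 1L)
    avgs[[2]]$window_start - avgs[[1]]$window_start else NA_real_
  # rebuild the full grid so skipped windows appear as gaps
  if (!is.na(step) && step > 0) {
    grid <- seq(min(centers), max(centers), by = step)
    v <- rep(NA_real_, length(grid))
    v[match(round(centers / step), round(grid / step))] <- vals
    metric_timecourse(grid, v, metric, step)
  } else {
    metric_timecourse(centers, vals, metric, step)
  }
}
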