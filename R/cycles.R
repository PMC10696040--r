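#' Burst-detection parameters
#'
#' Tuning knobs for [detect_bursts()]. The onset threshold sits `k_on`
#' robust SDs above a rolling low-quantile baseline, with a relative floor
#' (`floor_frac` of the trace's dynamic range) so detection also works on
#' noise-free envelopes. A candidate burst must stay above threshold for
#' `min_dur` seconds; candidates separated by less than the merge gap
#' (`merge_frac` of the median cycle duration) are merged. The inspiratory
#' offset — the onset of the sharp terminal decrease — uses a smoothed
#' derivative criterion with fraction `d_frac` (see [detect_bursts()]).
#'
#' @param k_on Onset threshold in robust SDs above baseline.
#' @param min_dur Minimum supra-threshold duration (s).
#' @param d_frac Derivative-threshold fraction for the terminal fall.
#' @param baseline_q Quantile for the rolling baseline estimate.
#' @param baseline_win Rolling-baseline window (s).
#' @param merge_frac Merge gap as a fraction of the median cycle duration.
#' @param floor_frac Threshold floor as a fraction of the dynamic range.
#' @param slope_win Smoothing window for the derivative estimate (s).
#' @param onset_refine Span (s) ahead of the threshold crossing used to
#'   estimate the local burst level; the onset is refined to the crossing
#'   of half that level, which makes onset latency independent of burst
#'   amplitude (a fixed threshold is reached later on smaller bursts).
#' @return A list of class `rb_burst_params`.
#' @export
burst_params <- function(k_on = 3, min_dur = 0.1, d_frac = 0.5,
                         baseline_q = 0.1, baseline_win = 5,
                         merge_frac = 0.3, floor_frac = 0.1,
                         slope_win = 0.15, onset_refine = 0.1) {
  p <- list(k_on = k_on, min_dur = min_dur, d_frac = d_frac,
            baseline_q = baseline_q, baseline_win = baseline_win,
            merge_frac = merge_frac, floor_frac = floor_frac,
            slope_win = slope_win, onset_refine = onset_refine)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all burst parameters must be single positive numbers")
  class(p) <- "rb_burst_params"
  p
}

# internal: rolling low-quantile baseline, evaluated on a 1-s hop grid and
# linearly interpolated back to every sample
rolling_baseline <- function(x, fs, q, win) {
  n <- length(x)
  hop <- max(1L, round(fs))
  half <- round(win * fs / 2)
  centers <- seq(1L, n, by = hop)
  bq <- vapply(centers, function(i)
    stats::quantile(x[max(1L, i - half):min(n, i + half)], q, names = FALSE),
    numeric(1))
  if (length(centers) == 1L) return(rep(bq, n))
  stats::approx(centers, bq, xout = seq_len(n), rule = 2)$y
}

# internal: centered moving mean (shrinking edges) of a plain numeric vector
moving_mean <- function(x, L) {
  n <- length(x)
  L <- max(1L, as.integer(L))
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect phrenic (inspiratory) bursts in an integrated trace
#'
#' Finds inspiratory bursts in an integrated nerve trace. Burst **onset** is
#' the upward crossing of a rolling baseline plus `k_on` robust SDs of the
#' between-burst noise, sustained for at least `min_dur` seconds, refined to
#' the half-rise crossing of the local burst level so that onset latency
#' does not depend on burst amplitude. The
#' **offset** is the onset of the sharp terminal decrease, operationalized
#' with a derivative criterion: the smoothed derivative must fall below
#' `-d_frac * (peak - baseline) / Ti_est`, which localizes the steep fall
#' region; within that region the offset is refined to the half-amplitude
#' crossing, which for an abrupt (step-like) fall recovers the true fall
#' time to within about one smoothing window. The **peak** is the maximum
#' between onset and offset.
#'
#' @param ipna An integrated [trace()] (the \eqn{\int}PNA).
#' @param params A [burst_params()] object.
#' @return A data frame of class `rb_bursts` with one row per burst and
#'   columns `onset`, `peak_time`, `offset` (s), `peak_amp`, `baseline_amp`
#'   (a.u.). Empty when no crossing occurs.
#' @export
detect_bursts <- function(ipna, params = burst_params()) {
  stopifnot(inherits(ipna, "rb_trace"))
  if (ipna$kind != "integrated")
    stop("`ipna` must be an integrated trace (see integrate_trace())")
  stopifnot(inherits(params, "rb_burst_params"))
  x <- ipna$samples; fs <- ipna$fs; n <- length(x)
  empty <- data.frame(onset = numeric(0), peak_time = numeric(0),
                      offset = numeric(0), peak_amp = numeric(0),
                      baseline_amp = numeric(0))
  class(empty) <- c("rb_bursts", "data.frame")
  if (n < 10L) return(empty)

  b <- rolling_baseline(x, fs, params$baseline_q, params$baseline_win)
  resid <- x - b
  quiet <- resid[resid <= stats::quantile(resid, 0.5)]
  noise_sd <- stats::mad(quiet, center = stats::median(quiet))
  rng <- stats::quantile(x, 0.95, names = FALSE) - b
  thr <- b + pmax(params$k_on * noise_sd, params$floor_frac * pmax(rng, 0))

  above <- x > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])

  merge_regions <- function(reg, gap_n) {
    if (nrow(reg) < 2L) return(reg)
    out <- reg[1, , drop = FALSE]
    for (i in 2:nrow(reg)) {
      if (reg[i, 1] - out[nrow(out), 2] <= gap_n)
        out[nrow(out), 2] <- reg[i, 2]
      else out <- rbind(out, reg[i, ])
    }
    out
  }
  # two passes: a provisional merge, then a merge gap tied to the median
  # inter-onset interval
  reg <- merge_regions(reg, round(0.2 * fs))
  reg <- reg[reg[, 2] - reg[, 1] + 1L >= round(params$min_dur * fs), , drop = FALSE]
  if (!nrow(reg)) return(empty)
  if (nrow(reg) >= 3L) {
    med_ttot <- stats::median(diff(reg[, 1])) / fs
    reg <- merge_regions(reg, round(params$merge_frac * med_ttot * fs))
    reg <- reg[reg[, 2] - reg[, 1] + 1L >= round(params$min_dur * fs), , drop = FALSE]
  }
  if (!nrow(reg)) return(empty)

  # smoothed derivative for the sharp-decrease criterion
  L2 <- max(3L, round(params$slope_win * fs))
  xs <- moving_mean(x, L2)
  h <- max(1L, L2 %/% 2L)
  d <- numeric(n)
  core <- (h + 1L):(n - h)
  d[core] <- (xs[core + h] - xs[core - h]) * fs / (2 * h)

  nb <- nrow(reg)
  onset <- peak_time <- offset <- peak_amp <- baseline_amp <- numeric(nb)
  h_on <- max(1L, round(params$onset_refine * fs))
  for (i in seq_len(nb)) {
    i1 <- reg[i, 1]; i2 <- reg[i, 2]
    i_prev <- if (i > 1L) reg[i - 1L, 2] + 1L else 1L
    i_next <- if (i < nb) reg[i + 1L, 1] - 1L else n
    base_i <- b[i1]
    # refine the onset: crossing of half the local burst level, which is
    # invariant to the burst's amplitude scale
    lvl <- base_i + 0.5 * (x[min(n, i1 + h_on)] - base_i)
    j <- i1
    if (x[j] >= lvl) {
      while (j > i_prev && x[j - 1L] >= lvl) j <- j - 1L
    } else {
      while (j < i2 && x[j] < lvl) j <- j + 1L
    }
    i1 <- j
    seg <- i1:min(i2 + round(0.2 * fs), i_next)
    ipk <- seg[which.max(x[seg])]
    pk <- x[ipk]
    ti_est <- (i2 - i1 + 1L) / fs
    thr_slope <- -params$d_frac * (pk - base_i) / ti_est
    srch <- ipk:i_next
    j_star <- srch[which.min(d[srch])]
    if (d[j_star] < thr_slope) {
      j <- j_star
      while (j > ipk && d[j - 1L] < thr_slope) j <- j - 1L
      run_start <- j
      half_lv <- (pk + base_i) / 2
      below <- run_start:i_next
      cross <- below[x[below] < half_lv]
      i_off <- if (length(cross) &&
                   (cross[1] - run_start) / fs <= 2 * params$slope_win)
        cross[1] else run_start
    } else {
      # no steep fall: fall back to the threshold down-crossing
      i_off <- i2
    }
    i_off <- max(i_off, i1 + 1L)
    onset[i] <- ipna$t0 + (i1 - 1L) / fs
    offset[i] <- ipna$t0 + (i_off - 1L) / fs
    ipk2 <- i1 - 1L + which.max(x[i1:i_off])
    peak_time[i] <- ipna$t0 + (ipk2 - 1L) / fs
    peak_amp[i] <- x[ipk2]
    baseline_amp[i] <- max(0, base_i)
  }
  out <- data.frame(onset = onset, peak_time = peak_time, offset = offset,
                    peak_amp = peak_amp, baseline_amp = baseline_amp)
  class(out) <- c("rb_bursts", "data.frame")
  out
}

#' Segment respiratory cycles from detected bursts
#'
#' A respiratory cycle spans from one inspiratory offset to the next
#' (`Ttot_k = offset_{k+1} - offset_k`). The inspiratory duration assigned
#' to a cycle is, by default, that of the inspiration **terminating** the
#' cycle (burst `k+1`), so `Te = Ttot - Ti` is the expiratory pause actually
#' contained in the cycle; the alternative convention (the inspiration
#' opening the cycle) is available via `convention = "opening"`. The
#' expiratory duration is obtained by subtraction, the inspiratory ratio is
#' `Ti / Ttot`, and the instantaneous frequency is `60 / Ttot`
#' (cycles/min). Cycles with non-positive `Te` (overlapping bursts) are
#' excluded with a warning and counted in the `excluded` attribute.
#'
#' @param bursts An `rb_bursts` data frame from [detect_bursts()].
#' @param fs Sampling rate of the source trace (Hz), used for the
#'   `Ti + Te = Ttot` bookkeeping tolerance.
#' @param convention Which inspiration's `Ti` belongs to an
#'   offset-to-offset cycle: `"terminating"` (default) or `"opening"`.
#' @return A data frame of class `rb_cycles` with columns `t_ref` (the
#'   closing offset time), `Ti`, `Te`, `Ttot`, `ratio`, `f_inst` and
#'   `amp_pna` (peak minus baseline of the cycle's inspiration).
#' @export
segment_cycles <- function(bursts, fs,
                           convention = c("terminating", "opening")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(bursts))
  empty <- data.frame(t_ref = numeric(0), Ti = numeric(0), Te = numeric(0),
                      Ttot = numeric(0), ratio = numeric(0),
                      f_inst = numeric(0), amp_pna = numeric(0))
  class(empty) <- c("rb_cycles", "data.frame")
  attr(empty, "excluded") <- 0L
  nb <- nrow(bursts)
  if (nb < 2L) return(empty)
  k <- seq_len(nb - 1L)
  ttot <- bursts$offset[k + 1L] - bursts$offset[k]
  src <- if (convention == "terminating") k + 1L else k
  ti <- bursts$offset[src] - bursts$onset[src]
  te <- ttot - ti
  amp <- bursts$peak_amp[src] - bursts$baseline_amp[src]
  keep <- te > 0 & ttot > 0
  n_excl <- sum(!keep)
  if (n_excl)
    warning(sprintf("%d cycle(s) with non-positive expiratory duration excluded", n_excl))
  out <- data.frame(t_ref = bursts$offset[k + 1L][keep], Ti = ti[keep],
                    Te = te[keep], Ttot = ttot[keep],
                    ratio = (ti / ttot)[keep], f_inst = (60 / ttot)[keep],
                    amp_pna = amp[keep])
  class(out) <- c("rb_cycles", "data.frame")
  attr(out, "excluded") <- n_excl
  out
}

#' Per-cycle metrics on the common sliding-window grid
#'
#' Averages the per-cycle metrics within 10-s bins (half-open
#' `[k*step, (k+1)*step)` on the cycle reference times). Respiratory
#' frequency is `60 / mean(Ttot)` per bin by default; a count-based
#' alternative (`cycles per bin * 60 / step`) is available. Empty bins are
#' gaps (`NA`), never zeros.
#'
#' @param cycles An `rb_cycles` data frame.
#' @param step Grid step (s, default 10).
#' @param t_range Optional time range the grid must cover.
#' @param f_method `"mean_ttot"` (default) or `"count"`.
#' @return A named list of [metric_timecourse()] objects: `f`, `Ti`, `Te`,
#'   `ratio`.
#' @export
metric_timecourses <- function(cycles, step = 10, t_range = NULL,
                               f_method = c("mean_ttot", "count")) {
  f_method <- match.arg(f_method)
  stopifnot(is.data.frame(cycles))
  if (!nrow(cycles)) stop("need at least one cycle")
  tc <- list()
  for (m in c("Ti", "Te", "ratio")) {
    bm <- bin_mean(cycles$t_ref, cycles[[m]], step, t_range)
    tc[[m]] <- metric_timecourse(bm$time, bm$value, m, step)
  }
  bt <- bin_mean(cycles$t_ref, cycles$Ttot, step, t_range)
  fval <- if (f_method == "mean_ttot") 60 / bt$value else {
    cnt <- vapply(bt$time, function(ct)
      sum(cycles$t_ref %inco% c(ct - step / 2, ct + step / 2)), numeric(1))
    ifelse(is.na(bt$value), NA_real_, cnt * 60 / step)
  }
  tc$f <- metric_timecourse(bt$time, fval, "f", step)
  tc[c("f", "Ti", "Te", "ratio")]
}
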