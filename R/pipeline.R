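#' Analyze one recording session
#'
#' Runs the full per-subject chain: rectify + smooth the nerve channels,
#' detect phrenic bursts, segment respiratory cycles, compute metric time
#' courses on the 10-s grid, burst-triggered averages over sliding 20-s
#' windows (amplitudes of \eqn{\int}PNA and post-inspiratory \eqn{\int}VNA),
#' heart rate from R waves, then percent-of-baseline normalization and
#' change rates relative to the first injection.
#'
#' @param session An `rb_session` with waveforms and injection events.
#' @param config An [pipeline_config()].
#' @return A list of class `rb_subject_result` with elements `bursts`,
#'   `cycles`, `timecourses` (named list of percent-normalized
#'   [metric_timecourse()]s for `amp_PNA`, `amp_postinsp_VNA`, `f`, `Ti`,
#'   `Te`, `ratio`, `HR`), `change_rates` (named numeric, %),
#'   `analysis_window`, and bookkeeping counts.
#' @export
analyze_session <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "rb_session"), inherits(config, "rb_pipeline_config"))
  if (is.null(session$traces)) stop("session has no waveforms")
  for (ch in c("PNA", "VNA", "ECG"))
    if (is.null(session$traces[[ch]]))
      stop(sprintf("session is missing channel '%s'", ch))
  if (is.null(session$events$injection) || !length(session$events$injection$times))
    stop("session has no injection events; cannot compute drug response")
  injection <- session$events$injection$times[1]

  fs <- session$traces$PNA$fs
  dur <- trace_duration(session$traces$PNA)
  span <- c(session$traces$PNA$t0, session$traces$PNA$t0 + dur)

  ipna <- integrate_trace(session$traces$PNA, config$integrate_window)
  ivna <- integrate_trace(session$traces$VNA, config$integrate_window)

  bursts <- detect_bursts(ipna, config$burst)
  if (nrow(bursts) < 3L) stop("too few bursts detected to segment cycles")
  cycles <- segment_cycles(bursts, fs, config$ti_convention)
  tcs <- metric_timecourses(cycles, step = config$avg_step, t_range = span,
                            f_method = config$f_method)

  med_ti <- stats::median(cycles$Ti)
  med_te <- stats::median(cycles$Te)
  med_ttot <- stats::median(cycles$Ttot)
  lag <- c(-1, 1.5 * med_ttot)
  avgs <- triggered_average(list(PNA = ipna, VNA = ivna),
                            triggers = bursts$onset,
                            window = config$avg_window, step = config$avg_step,
                            lag = lag, t_range = span)
  if (!length(avgs)) stop("triggered averaging produced no windows")
  tcs$amp_PNA <- amplitude_timecourse(avgs, "PNA", "burst",
                                      burst_lag = c(0, 1.2 * med_ti))
  # start the post-inspiratory window one smoothing margin past the phrenic
  # offset so the smeared inspiratory edge cannot leak into the measurement
  tcs$amp_postinsp_VNA <- amplitude_timecourse(
    avgs, "VNA", "postinsp",
    pna_offset_lag = med_ti + 2 * config$integrate_window,
    w_pi = 0.5 * med_te)

  rpeaks <- detect_r_peaks(session$traces$ECG)
  tcs$HR <- if (length(rpeaks$times) >= 2L)
    heart_rate(rpeaks, step = config$avg_step, t_range = span)
  else metric_timecourse(numeric(0), numeric(0), "HR", config$avg_step)

  metrics <- c("amp_PNA", "amp_postinsp_VNA", "f", "Ti", "Te", "ratio", "HR")
  tcs <- tcs[metrics]
  for (m in metrics)
    if (nrow(tcs[[m]]))
      tcs[[m]] <- percent_of_baseline(tcs[[m]], injection, config$baseline_dur)
  change <- vapply(metrics, function(m)
    if (nrow(tcs[[m]])) change_rate(tcs[[m]], config$analysis_window, injection)
    else NA_real_, numeric(1))

  structure(list(bursts = bursts, cycles = cycles, timecourses = tcs,
                 change_rates = change, injection_time = injection,
                 analysis_window = config$analysis_window,
                 n_excluded_cycles = attr(cycles, "excluded"),
                 n_skipped_triggers = sum(vapply(avgs, `[[`, numeric(1), "n_skipped"))),
            class = "rb_subject_result")
}

#' Group statistics over a cohort of subject results
#'
#' One-sample t-tests of the per-subject change rates against 100% (no
#' change) for every metric, and per-metric repeated-measures ANOVA with
#' Dunnett comparisons of each post-baseline timepoint against the control
#' timepoint (the last bin before the injection).
#'
#' @param results List of `rb_subject_result` objects.
#' @param config The [pipeline_config()] used to produce them.
#' @return A list of class `rb_group_result`: `change_rates` (subjects x
#'   metrics matrix), `tests` (list of `rb_group_stats` per metric),
#'   `dunnett` (list of `rb_rm_dunnett` per metric).
#' @export
group_response <- function(results, config = pipeline_config()) {
  stopifnot(length(results) >= 2L)
  metrics <- names(results[[1]]$change_rates)
  cr <- t(vapply(results, `[[`, numeric(length(metrics)), "change_rates"))
  colnames(cr) <- metrics
  tests <- lapply(metrics, function(m) {
    v <- cr[, m]; v <- v[is.finite(v)]
    if (length(v) >= 2L) one_sample_t(v, 100, metric = m) else NULL
  })
  names(tests) <- metrics

  injection <- results[[1]]$injection_time
  dunnett <- lapply(metrics, function(m) {
    rows <- lapply(results, function(r) {
      tc <- r$timecourses[[m]]
      if (!nrow(tc)) return(NULL)
      sel <- tc$time >= injection - config$baseline_dur &
             tc$time <= injection + config$rm_horizon
      stats::setNames(tc$percent[sel], sprintf("%.0f", tc$time[sel]))
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) < 2L) return(NULL)
    times <- names(rows[[1]])
    if (!all(vapply(rows, function(r) identical(names(r), times), logical(1))))
      return(NULL)
    mat <- do.call(rbind, rows)
    pre <- which(as.numeric(times) < injection)
    if (!length(pre)) return(NULL)
    tryCatch(rm_anova_dunnett(mat, control = max(pre)),
             error = function(e) NULL)
  })
  names(dunnett) <- metrics
  structure(list(change_rates = cr, tests = tests, dunnett = dunnett),
            class = "rb_group_result")
}

#' Run the complete pipeline and write the report bundle
#'
#' Simulates (or accepts) a cohort of sessions, analyzes every subject,
#' computes group statistics, and writes the output tables and the run
#' manifest to `out_dir`. Outputs are deterministic given the config (the
#' manifest deliberately carries no timestamps): `cycles.csv` (per-subject
#' cycle tables), `timecourses.csv` (metric, time, value, percent),
#' `change_rates.csv`, `group_stats.csv`, `dunnett.csv` and
#' `manifest.json`.
#'
#' @param config An [pipeline_config()].
#' @param sessions Optional list of `rb_session` objects; when `NULL`, a
#'   cohort of `config$n_subjects` is simulated from `config$synth` (with
#'   `config$seed` as master seed) and `config$protocol`.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return An `rb_group_result` (invisibly when writing), with the
#'   per-subject results attached as attribute `"subjects"`.
#' @export
run_pipeline <- function(config, sessions = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "rb_pipeline_config"))
  if (is.null(sessions)) {
    syn <- config$synth
    syn$seed <- config$seed
    sessions <- simulate_cohort(config$n_subjects, syn, config$protocol)
  }
  if (!length(sessions)) stop("no sessions to analyze")
  results <- lapply(seq_along(sessions), function(i) {
    tryCatch(analyze_session(sessions[[i]], config),
             error = function(e)
               stop(sprintf("subject %d failed in analysis: %s", i,
                            conditionMessage(e)), call. = FALSE))
  })
  grp <- if (length(results) >= 2L) group_response(results, config) else
    structure(list(change_rates = t(as.matrix(results[[1]]$change_rates)),
                   tests = list(), dunnett = list()),
              class = "rb_group_result")
  attr(grp, "subjects") <- results

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cyc <- data.table::rbindlist(lapply(seq_along(results), function(i)
      cbind(subject = i, as.data.frame(results[[i]]$cycles))))
    data.table::fwrite(cyc, file.path(out_dir, "cycles.csv"))
    tc_all <- data.table::rbindlist(lapply(seq_along(results), function(i) {
      r <- results[[i]]
      data.table::rbindlist(lapply(names(r$timecourses), function(m) {
        tc <- r$timecourses[[m]]
        if (!nrow(tc)) return(NULL)
        data.table::data.table(subject = i, metric = m, time = tc$time,
                               value = tc$value, percent = tc$percent)
      }))
    }))
    data.table::fwrite(tc_all, file.path(out_dir, "timecourses.csv"))
    cr <- data.table::data.table(subject = seq_len(nrow(grp$change_rates)),
                                 grp$change_rates)
    data.table::fwrite(cr, file.path(out_dir, "change_rates.csv"))
    gs <- data.table::rbindlist(lapply(Filter(Negate(is.null), grp$tests),
      function(s) data.table::data.table(
        metric = s$metric, n = s$n, mean = s$mean, sem = s$sem,
        statistic = s$statistic, df = s$df, p = s$p,
        significant = s$significant, test = s$test)))
    data.table::fwrite(gs, file.path(out_dir, "group_stats.csv"))
    dn <- data.table::rbindlist(lapply(names(grp$dunnett), function(m) {
      d <- grp$dunnett[[m]]
      if (is.null(d)) return(NULL)
      data.table::data.table(metric = m, control = d$control, d$dunnett,
                             anova_F = d$anova$F, anova_p = d$anova$p)
    }))
    data.table::fwrite(dn, file.path(out_dir, "dunnett.csv"))
    manifest <- list(
      package = "respburst",
      version = as.character(utils::packageVersion("respburst")),
      config = config_as_list(config),
      config_fingerprint = config_fingerprint(config),
      n_subjects = length(results),
      n_excluded_cycles = sum(vapply(results, `[[`, numeric(1), "n_excluded_cycles")),
      n_skipped_triggers = sum(vapply(results, `[[`, numeric(1), "n_skipped_triggers")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(grp))
  }
  grp
}

#' @export
print.rb_group_result <- function(x, ...) {
  cat(sprintf("<rb_group_result> %d subjects\n", nrow(x$change_rates)))
  cat("Group change rates (% of baseline, mean +/- SEM):\n")
  for (s in Filter(Negate(is.null), x$tests))
    cat(sprintf("  %-18s %6.1f +/- %4.1f  (t=%.3g, p=%.3g)%s\n",
                s$metric, s$mean, s$sem, s$statistic, s$p,
                if (s$significant) " *" else ""))
  invisible(x)
}
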