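#' Save a recording session to a plain-text container
#'
#' Writes one directory per session: `session.json` (channel metadata,
#' protocol, events) plus one CSV per channel and a `truth.csv` when ground
#' truth is present. Sample values are written in shortest round-trip
#' decimal representation, so a save/load round trip reproduces the arrays
#' bit for bit.
#'
#' @param session An `rb_session` with waveforms.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "rb_session"))
  if (is.null(session$traces)) stop("session has no waveforms to save")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "respburst-session",
    version = 1L,
    channels = lapply(session$traces, function(tr)
      list(channel = tr$channel, fs = tr$fs, t0 = tr$t0, kind = tr$kind,
           n = length(tr$samples), file = paste0(tr$channel, ".csv"))),
    events = lapply(session$events, function(ev)
      list(label = ev$label, times = ev$times)),
    protocol = unclass(session$protocol),
    config = if (!is.null(session$config)) unclass(session$config) else NULL,
    has_truth = !is.null(session$truth) && nrow(session$truth) > 0)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # %.17g guarantees the decimal text parses back to the identical double
  for (tr in session$traces)
    writeLines(c("value", sprintf("%.17g", tr$samples)),
               file.path(path, paste0(tr$channel, ".csv")))
  if (meta$has_truth) {
    tru <- session$truth
    lines <- c(paste(names(tru), collapse = ","),
               do.call(paste, c(lapply(tru, function(col) sprintf("%.17g", col)),
                                sep = ",")))
    writeLines(lines, file.path(path, "truth.csv"))
  }
  invisible(path)
}

#' Load a recording session saved by [save_session()]
#'
#' Reconstructs traces and events losslessly. A missing or inconsistent
#' field (no sampling rate, truncated channel file) raises a format error
#' naming the problem; no partial session is returned.
#'
#' @param path Session directory.
#' @return An `rb_session`.
#' @export
load_session <- function(path) {
  meta_file <- file.path(path, "session.json")
  if (!file.exists(meta_file))
    stop(sprintf("not a session container: missing %s", meta_file))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (is.null(meta$channels) || !length(meta$channels))
    stop("format error: 'channels' missing from session.json")
  traces <- list()
  for (ch in meta$channels) {
    for (f in c("channel", "fs", "kind", "n", "file"))
      if (is.null(ch[[f]]))
        stop(sprintf("format error: channel field '%s' missing", f))
    csv <- file.path(path, ch$file)
    if (!file.exists(csv))
      stop(sprintf("format error: channel file '%s' missing", ch$file))
    v <- data.table::fread(csv)$value
    if (length(v) != ch$n)
      stop(sprintf("format error: channel '%s' truncated (%d of %d samples)",
                   ch$channel, length(v), ch$n))
    traces[[ch$channel]] <- trace(v, ch$fs, channel = ch$channel,
                                  t0 = if (is.null(ch$t0)) 0 else ch$t0,
                                  kind = ch$kind)
  }
  events <- lapply(meta$events, function(ev)
    event_series(as.numeric(unlist(ev$times)), ev$label))
  names(events) <- vapply(meta$events, `[[`, "", "label")
  protocol <- NULL
  if (!is.null(meta$protocol)) {
    protocol <- meta$protocol
    protocol$injection_times <- as.numeric(unlist(protocol$injection_times))
    protocol$pre_duration <- as.numeric(protocol$pre_duration)
    protocol$post_duration <- as.numeric(protocol$post_duration)
    class(protocol) <- "rb_protocol"
  }
  truth <- NULL
  if (isTRUE(meta$has_truth)) {
    tf <- file.path(path, "truth.csv")
    if (!file.exists(tf)) stop("format error: truth.csv missing")
    truth <- as.data.frame(data.table::fread(tf))
  }
  config <- NULL
  if (!is.null(meta$config)) {
    config <- meta$config
    class(config) <- "rb_synth_config"
  }
  structure(list(traces = traces, events = events, protocol = protocol,
                 truth = truth, config = config),
            class = "rb_session")
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain plus the synthetic-data
#' config and protocol, so a run is fully described (and reproducible) from
#' one object. Validated on construction, before any computation.
#'
#' @param synth An [synth_config()].
#' @param protocol An [drug_protocol()].
#' @param n_subjects Cohort size for simulated runs.
#' @param integrate_window Rectify-and-smooth window (s), default 0.05.
#' @param burst A [burst_params()] object.
#' @param avg_window,avg_step Triggered-averaging window and step (s),
#'   defaults 20 and 10.
#' @param baseline_dur Baseline window (s), default 100.
#' @param analysis_window Post-injection change-rate window (s), relative to
#'   the injection.
#' @param rm_horizon How far past the injection (s) the repeated-measures
#'   ANOVA / Dunnett time-course comparison extends.
#' @param f_method Frequency convention, see [metric_timecourses()].
#' @param ti_convention See [segment_cycles()].
#' @param seed Master seed for the run.
#' @return A list of class `rb_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), protocol = drug_protocol(),
                            n_subjects = 3, integrate_window = 0.05,
                            burst = burst_params(), avg_window = 20,
                            avg_step = 10, baseline_dur = 100,
                            analysis_window = c(60, 180), rm_horizon = 240,
                            f_method = c("mean_ttot", "count"),
                            ti_convention = c("terminating", "opening"),
                            seed = 1L) {
  stopifnot(inherits(synth, "rb_synth_config"), inherits(protocol, "rb_protocol"),
            inherits(burst, "rb_burst_params"))
  f_method <- match.arg(f_method)
  ti_convention <- match.arg(ti_convention)
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (!is.numeric(integrate_window) || integrate_window <= 0)
    stop("`integrate_window` must be positive")
  if (!is.numeric(baseline_dur) || baseline_dur <= 0)
    stop("`baseline_dur` must be positive")
  if (baseline_dur > protocol$pre_duration)
    stop("`baseline_dur` exceeds the pre-injection period")
  if (avg_window <= 0 || avg_step <= 0) stop("window and step must be positive")
  if (length(analysis_window) != 2L || analysis_window[2] <= analysis_window[1] ||
      analysis_window[1] < 0)
    stop("`analysis_window` must be an increasing post-injection interval")
  if (analysis_window[2] > protocol$post_duration)
    stop("`analysis_window` extends beyond the recorded post-injection period")
  structure(list(synth = synth, protocol = protocol,
                 n_subjects = as.integer(n_subjects),
                 integrate_window = integrate_window, burst = burst,
                 avg_window = avg_window, avg_step = avg_step,
                 baseline_dur = baseline_dur,
                 analysis_window = as.numeric(analysis_window),
                 rm_horizon = rm_horizon, f_method = f_method,
                 ti_convention = ti_convention, seed = as.integer(seed)),
            class = "rb_pipeline_config")
}

# internal: plain nested list for serialization (strips S3 classes)
config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Save / load a pipeline configuration (JSON or YAML)
#'
#' The format follows the file extension: `.yaml`/`.yml` for YAML,
#' anything else is JSON.
#'
#' @param config An `rb_pipeline_config`.
#' @param path File path.
#' @return `save_pipeline_config` returns `path` invisibly;
#'   `load_pipeline_config` returns an `rb_pipeline_config`.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "rb_pipeline_config"))
  x <- config_as_list(config)
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- do.call(synth_config, x$synth[setdiff(names(x$synth), character(0))])
  prot <- drug_protocol(site = x$protocol$site, agent = x$protocol$agent,
                        injection_times = unlist(x$protocol$injection_times),
                        post_duration = x$protocol$post_duration)
  burst <- do.call(burst_params, x$burst)
  pipeline_config(synth = syn, protocol = prot, n_subjects = x$n_subjects,
                  integrate_window = x$integrate_window, burst = burst,
                  avg_window = x$avg_window, avg_step = x$avg_step,
                  baseline_dur = x$baseline_dur,
                  analysis_window = unlist(x$analysis_window),
                  rm_horizon = x$rm_horizon, f_method = x$f_method,
                  ti_convention = x$ti_convention, seed = x$seed)
}

# internal: small deterministic fingerprint of a serialized config
config_fingerprint <- function(config) {
  s <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}
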