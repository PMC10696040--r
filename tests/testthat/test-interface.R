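tiny_pipeline_config <- function(seed = 2L, n = 2L) {
  pipeline_config(
    synth = quick_config(fs = 250, seed = seed),
    protocol = quick_protocol(post_duration = 240, agent = "HA"),
    n_subjects = n, analysis_window = c(90, 150), rm_horizon = 180,
    seed = seed)
}

test_that("session save/load round trip is lossless", {
  s <- simulate_subject(quick_config(fs = 250, seed = 13L), quick_protocol(30))
  d <- file.path(tempdir(), "sess_rt")
  save_session(s, d)
  s2 <- load_session(d)
  for (ch in c("PNA", "VNA", "ECG", "PP")) {
    expect_identical(s2$traces[[ch]]$samples, s$traces[[ch]]$samples)
    expect_identical(s2$traces[[ch]]$fs, s$traces[[ch]]$fs)
  }
  expect_identical(s2$events$injection$times, s$events$injection$times)
  expect_equal(as.data.frame(s2$truth), s$truth)
  expect_identical(s2$protocol$injection_times, s$protocol$injection_times)
  unlink(d, recursive = TRUE)
})

test_that("a session without injection events loads but the response stage refuses", {
  s <- simulate_subject(quick_config(fs = 250, seed = 13L), quick_protocol(30))
  s$events <- list()
  d <- file.path(tempdir(), "sess_noinj")
  save_session(s, d)
  s2 <- load_session(d)
  expect_true(inherits(s2, "rb_session"))
  expect_error(analyze_session(s2, tiny_pipeline_config()),
               "no injection events")
  unlink(d, recursive = TRUE)
})

test_that("a truncated container is a format error, not a partial session", {
  s <- simulate_subject(quick_config(fs = 250, seed = 13L), quick_protocol(30))
  d <- file.path(tempdir(), "sess_trunc")
  save_session(s, d)
  # drop half of the PNA samples
  v <- readLines(file.path(d, "PNA.csv"))
  writeLines(v[1:101], file.path(d, "PNA.csv"))
  expect_error(load_session(d), "truncated")
  save_session(s, d)  # restore, then remove a whole channel file
  file.remove(file.path(d, "VNA.csv"))
  expect_error(load_session(d), "missing")
  expect_error(load_session(file.path(tempdir(), "no_such_dir")),
               "not a session container")
  unlink(d, recursive = TRUE)
})

test_that("pipeline config validates before any computation", {
  expect_error(pipeline_config(baseline_dur = 0), "baseline_dur")
  expect_error(pipeline_config(analysis_window = c(180, 60)), "analysis_window")
  expect_error(pipeline_config(
    protocol = quick_protocol(post_duration = 100),
    analysis_window = c(60, 180)), "beyond the recorded")
  expect_error(pipeline_config(n_subjects = 0), "n_subjects")
})

test_that("config save/load round trips through JSON and YAML", {
  cfg <- tiny_pipeline_config(seed = 31L)
  fj <- tempfile(fileext = ".json")
  fy <- tempfile(fileext = ".yaml")
  save_pipeline_config(cfg, fj)
  save_pipeline_config(cfg, fy)
  cj <- load_pipeline_config(fj)
  cy <- load_pipeline_config(fy)
  expect_equal(config_as_list(cj), config_as_list(cfg))
  expect_equal(config_as_list(cy), config_as_list(cfg))
  file.remove(fj, fy)
})

test_that("run_pipeline writes a deterministic report bundle", {
  cfg <- tiny_pipeline_config(seed = 17L)
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  run_pipeline(cfg, out_dir = d1)
  run_pipeline(cfg, out_dir = d2)
  files <- c("cycles.csv", "timecourses.csv", "change_rates.csv",
             "group_stats.csv", "dunnett.csv", "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true(nzchar(man$config_fingerprint))
  expect_equal(man$n_subjects, 2L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("null-protocol cohort shows no significant change on any metric", {
  # deterministic (noise-free) null: change rates are exactly 100 and the
  # zero-variance rule gives p = 1; the noisy-null rejection *rate* is
  # checked by the 500-replicate calibration test
  cfg <- pipeline_config(
    synth = clean_config(fs = 250, seed = 23L),
    protocol = quick_protocol(post_duration = 240, agent = "vehicle"),
    n_subjects = 3, analysis_window = c(90, 150), rm_horizon = 180,
    seed = 23L)
  grp <- run_pipeline(cfg)
  for (m in c("amp_PNA", "amp_postinsp_VNA", "f", "Ti", "Te", "ratio")) {
    expect_false(grp$tests[[m]]$significant)
    expect_equal(grp$tests[[m]]$mean, 100, tolerance = 1e-6)
  }
})

test_that("CLI simulate -> analyze composes to the same bytes as run", {
  cfg <- tiny_pipeline_config(seed = 29L)
  fcfg <- tempfile(fileext = ".json")
  save_pipeline_config(cfg, fcfg)
  d_sess <- file.path(tempdir(), "cli_sessions")
  d_an <- file.path(tempdir(), "cli_analyze")
  d_run <- file.path(tempdir(), "cli_run")
  suppressMessages({
    cli_main(c("simulate", "--config", fcfg, "--seed", "29", "--out", d_sess))
    cli_main(c("analyze", "--sessions", d_sess, "--out", d_an))
    cli_main(c("run", "--config", fcfg, "--seed", "29", "--out", d_run))
  })
  for (f in c("cycles.csv", "timecourses.csv", "change_rates.csv",
              "group_stats.csv", "dunnett.csv")) {
    expect_identical(readBin(file.path(d_an, f), "raw", file.size(file.path(d_an, f))),
                     readBin(file.path(d_run, f), "raw", file.size(file.path(d_run, f))))
  }
  expect_error(suppressMessages(cli_main(c("explode"))), "unknown subcommand")
  expect_error(suppressMessages(cli_main(c("run", "--config", fcfg))),
               "requires --")
  unlink(c(d_sess, d_an, d_run), recursive = TRUE)
  file.remove(fcfg)
})
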