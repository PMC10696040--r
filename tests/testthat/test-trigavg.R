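# a periodic integrated trace with identical triangular "cycles"
periodic_trace <- function(n_cycles = 12, period = 4, fs = 250, amp = 2,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- round(n_cycles * period * fs)
  tt <- (seq_len(n) - 1) / fs
  phase <- tt %% period
  v <- ifelse(phase < 1, amp * phase, 0)
  v <- v + if (noise_sd > 0) abs(rnorm(n, sd = noise_sd)) else 0
  trace(v, fs, "PNA", kind = "integrated")
}

test_that("triggered average equals the brute-force stack-and-mean", {
  set.seed(10)
  for (i in 1:10) {
    fs <- 200
    v <- abs(rnorm(4000))
    tr <- trace(v, fs, kind = "integrated")
    trig <- sort(runif(15, 2, 18))
    lag <- c(-0.5, 1)
    avgs <- triggered_average(list(PNA = tr), trig, window = 20, step = 10,
                              lag = lag)
    expect_equal(length(avgs), 1L)  # one complete 20-s window in [0, 20]
    ref <- brute_stack_mean(v, fs, 0, trig[trig >= 0 & trig < 20], lag)
    expect_lt(max(abs(avgs[[1]]$mean_traces$PNA - ref)), 1e-12)
  }
})

test_that("a single trigger reproduces the aligned segment exactly", {
  tr <- periodic_trace()
  avgs <- triggered_average(list(PNA = tr), 10.0, window = 20, step = 10,
                            lag = c(-1, 2))
  il <- round(-1 * tr$fs):round(2 * tr$fs)
  seg <- tr$samples[round(10 * tr$fs) + 1 + il]
  expect_identical(avgs[[1]]$mean_traces$PNA, seg)
  expect_equal(avgs[[1]]$n_triggers, 1L)
})

test_that("averaging identical noiseless cycles returns a single cycle", {
  tr <- periodic_trace(n_cycles = 20)
  trig <- seq(4, 72, by = 4)
  avgs <- triggered_average(list(PNA = tr), trig, window = 20, step = 10,
                            lag = c(-1, 3))
  one <- brute_stack_mean(tr$samples, tr$fs, 0, trig[3], c(-1, 3))
  for (a in avgs)
    expect_equal(a$mean_traces$PNA, one, tolerance = 1e-12)
})

test_that("residual noise after averaging shrinks like 1/sqrt(N)", {
  period <- 2; fs <- 250
  clean <- periodic_trace(n_cycles = 120, period = period, fs = fs)
  noisy <- trace(clean$samples + abs(rnorm(length(clean$samples), sd = 0.5)),
                 fs, kind = "integrated")
  trig <- seq(period, 118 * period, by = period)
  resid_sd <- function(window) {
    avgs <- triggered_average(list(PNA = noisy), trig, window = window,
                              step = window, lag = c(-0.5, 1.5))
    mean(vapply(avgs, function(a) {
      ref <- brute_stack_mean(clean$samples, fs, 0, trig[2], c(-0.5, 1.5))
      stats::sd(a$mean_traces$PNA - ref)
    }, numeric(1)))
  }
  r4 <- resid_sd(4 * period)   # 4 triggers per window
  r16 <- resid_sd(16 * period) # 16 triggers per window
  expect_gt(r4 / r16, 1.5)
  expect_lt(r4 / r16, 2.7)
})

test_that("shifting traces and triggers together leaves the average unchanged", {
  tr <- periodic_trace()
  trig <- seq(4, 40, by = 4)
  a1 <- triggered_average(list(PNA = tr), trig, lag = c(-1, 2))
  tr2 <- tr; tr2$t0 <- tr$t0 + 100
  a2 <- triggered_average(list(PNA = tr2), trig + 100, lag = c(-1, 2))
  expect_equal(length(a1), length(a2))
  for (i in seq_along(a1))
    expect_identical(a1[[i]]$mean_traces$PNA, a2[[i]]$mean_traces$PNA)
})

test_that("every trigger is counted in exactly the windows containing it", {
  tr <- periodic_trace(n_cycles = 20)
  trig <- seq(3, 77, by = 3.7)
  avgs <- triggered_average(list(PNA = tr), trig, window = 20, step = 10,
                            lag = c(-0.5, 0.5))
  for (a in avgs) {
    inside <- sum(trig >= a$window_start & trig < a$window_end) - a$n_skipped
    expect_equal(a$n_triggers, inside)
  }
})

test_that("amplitude is peak minus pre-trigger baseline, and scales linearly", {
  # averaged triangle peaking at 2.0 on a 0.2 baseline -> amplitude 1.8
  fs <- 1000
  lag_axis <- seq(-1, 2, by = 1 / fs)
  wave <- 0.2 + ifelse(lag_axis > 0 & lag_axis <= 0.5, 1.8 * lag_axis / 0.5,
                ifelse(lag_axis > 0.5 & lag_axis <= 1, 1.8 * (1 - lag_axis) / 0.5, 0))
  avg <- structure(list(window_start = 0, window_end = 20,
                        lag_axis = lag_axis,
                        mean_traces = list(PNA = wave), n_triggers = 5L,
                        n_skipped = 0L), class = "rb_trigavg")
  expect_equal(amplitude_from_average(avg, "PNA", burst_lag = c(0, 1.2)), 1.8,
               tolerance = 1e-6)
  # all-zero average -> 0
  avg0 <- avg; avg0$mean_traces$PNA <- numeric(length(lag_axis))
  expect_equal(amplitude_from_average(avg0, "PNA", burst_lag = c(0, 1.2)), 0)
  # exact linearity in the trace scale
  avg3 <- avg; avg3$mean_traces$PNA <- 3 * wave
  expect_identical(amplitude_from_average(avg3, "PNA", burst_lag = c(0, 1.2)),
                   3 * amplitude_from_average(avg, "PNA", burst_lag = c(0, 1.2)))
  expect_error(amplitude_from_average(avg, "VNA"), "not present")
  expect_error(amplitude_from_average(avg, "PNA", burst_lag = c(5, 6)), "empty")
})

test_that("post-inspiratory VNA amplitude reads the decrementing component", {
  fs <- 1000
  lag_axis <- seq(-1, 3, by = 1 / fs)
  # pure post-inspiratory exponential of initial height 1.0 after offset 0.9
  wave <- ifelse(lag_axis > 0.9, exp(-(lag_axis - 0.9) / 0.5), 0)
  avg <- structure(list(window_start = 0, window_end = 20,
                        lag_axis = lag_axis,
                        mean_traces = list(VNA = wave), n_triggers = 4L,
                        n_skipped = 0L), class = "rb_trigavg")
  expect_equal(postinsp_vna_amplitude(avg, pna_offset_lag = 0.9, w_pi = 1),
               1.0, tolerance = 2e-3)
  avg0 <- avg; avg0$mean_traces$VNA <- numeric(length(lag_axis))
  expect_equal(postinsp_vna_amplitude(avg0, 0.9, 1), 0)
  expect_error(postinsp_vna_amplitude(avg, 2.5, 1), "beyond the lag axis")
})

test_that("halving the generator envelope scale halves the measured amplitude", {
  p <- quick_protocol(60)
  a <- c(full = 1, half = 0.5)
  amps <- vapply(a, function(sc) {
    cfg <- quick_config(amp_pna0 = sc, seed = 21L)
    s <- simulate_subject(cfg, p)
    ipna <- integrate_trace(s$traces$PNA)
    b <- detect_bursts(ipna)
    avgs <- triggered_average(list(PNA = ipna), b$onset, lag = c(-1, 5))
    mean(vapply(avgs, amplitude_from_average, numeric(1), channel = "PNA",
                burst_lag = c(0, 1.2)))
  }, numeric(1))
  expect_equal(amps[["half"]] / amps[["full"]], 0.5, tolerance = 0.05)
})
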