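# build a clean integrated-trace envelope with ramp bursts at given onsets
ramp_trace <- function(onsets, ti, fs = 1000, dur = NULL, amp = 1,
                       onset_frac = 0.25) {
  if (is.null(dur)) dur <- max(onsets) + ti + 3
  n <- round(dur * fs)
  v <- numeric(n)
  for (o in onsets) {
    i1 <- round(o * fs) + 1L
    i2 <- round((o + ti) * fs)
    v[i1:i2] <- amp * (onset_frac + (1 - onset_frac) * (i1:i2 - i1) / (i2 - i1))
  }
  trace(v, fs, "PNA", kind = "integrated")
}

test_that("burst onsets on clean ramp bursts are recovered within a smoothing window", {
  onsets <- seq(2, 38, by = 4)
  tr <- ramp_trace(onsets, ti = 1, fs = 1000, dur = 42)
  b <- detect_bursts(tr)
  expect_equal(nrow(b), length(onsets))
  expect_lt(max(abs(b$onset - onsets)), 0.05)
  expect_lt(max(abs(b$offset - (onsets + 1))), 0.05)
  expect_true(all(b$onset < b$peak_time & b$peak_time <= b$offset))
  expect_true(all(b$peak_amp > b$baseline_amp & b$baseline_amp >= 0))
})

test_that("zero trace yields no bursts; non-integrated input is a type error", {
  z <- trace(numeric(5000), 500, kind = "integrated")
  expect_equal(nrow(detect_bursts(z)), 0L)
  expect_error(detect_bursts(trace(numeric(5000), 500, kind = "raw")),
               "integrated")
})

test_that("offset lands within one sample of an instantaneous fall", {
  # triangular burst: rise over [1, 2], instantaneous fall at t = 2
  fs <- 1000
  v <- numeric(10 * fs)
  i1 <- 1 * fs; i2 <- 2 * fs
  v[i1:i2] <- 2 * (i1:i2 - i1) / (i2 - i1)
  # second burst so the detector has context
  v[(5 * fs):(6 * fs)] <- 2 * ((5 * fs):(6 * fs) - 5 * fs) / fs
  b <- detect_bursts(trace(v, fs, kind = "integrated"))
  expect_gte(nrow(b), 1L)
  expect_lt(abs(b$offset[1] - 2), 1 / fs + 1e-9)
})

test_that("cycle segmentation implements the offset-to-offset definitions", {
  bursts <- data.frame(onset = c(-1, 3), peak_time = c(-0.5, 3.5),
                       offset = c(0, 4), peak_amp = c(2, 2),
                       baseline_amp = c(0, 0))
  cy <- segment_cycles(bursts, fs = 1000)
  expect_equal(cy$Ttot, 4)
  expect_equal(cy$Ti, 1)   # terminating inspiration: 4 - 3
  expect_equal(cy$Te, 3)
  expect_equal(cy$ratio, 0.25)
  expect_equal(cy$f_inst, 15)
  expect_equal(cy$t_ref, 4)
  # equal bursts every 5 s with Ti = 1 -> all cycles ratio 0.20
  onsets <- seq(0, 40, 5)
  b2 <- data.frame(onset = onsets, peak_time = onsets + 0.5,
                   offset = onsets + 1, peak_amp = 2, baseline_amp = 0)
  cy2 <- segment_cycles(b2, 1000)
  expect_true(all(cy2$ratio == 0.2))
  expect_true(all(cy2$Ttot == 5))
  # opening convention assigns the cycle's first inspiration
  b3 <- data.frame(onset = c(-1, 2.5), peak_time = c(-0.5, 3),
                   offset = c(0, 4), peak_amp = 2, baseline_amp = 0)
  expect_equal(segment_cycles(b3, 1000, "terminating")$Ti, 1.5)
  expect_equal(segment_cycles(b3, 1000, "opening")$Ti, 1)
  # fewer than 2 bursts: empty
  expect_equal(nrow(segment_cycles(b3[1, ], 1000)), 0L)
})

test_that("overlapping bursts are flagged and excluded, never silently dropped", {
  b <- data.frame(onset = c(0, 0.5, 8), peak_time = c(0.2, 2, 8.5),
                  offset = c(0.4, 4, 9), peak_amp = 2, baseline_amp = 0)
  # cycle 1: Ttot = 3.6 but terminating Ti = 3.5 -> Te = 0.1 ok;
  # force a negative Te with a long terminating burst
  b$onset[2] <- -1
  expect_warning(cy <- segment_cycles(b, 1000), "excluded")
  expect_equal(attr(cy, "excluded"), 1L)
})

test_that("ground-truth timing is recovered through the full detection chain", {
  cfg <- clean_config(fs = 1000, Ti0 = 0.9, Te0 = 3.1)
  s <- simulate_subject(cfg, quick_protocol(60))
  b <- detect_bursts(integrate_trace(s$traces$PNA))
  expect_equal(nrow(b), nrow(s$truth))
  expect_lt(max(abs(b$onset - s$truth$onset)), 0.05)
  expect_lt(max(abs(b$offset - s$truth$offset)), 0.05)
  cy <- segment_cycles(b, cfg$fs)
  expect_lt(max(abs(cy$Ti - 0.9)), 0.05)
  expect_lt(max(abs(cy$Te - 3.1)), 0.05)
})

test_that("cycle algebra holds on noisy synthetic sessions", {
  for (seed in c(3L, 11L)) {
    cfg <- quick_config(seed = seed)
    s <- simulate_subject(cfg, quick_protocol(60))
    cy <- segment_cycles(detect_bursts(integrate_trace(s$traces$PNA)), cfg$fs)
    expect_gt(nrow(cy), 10)
    expect_lt(max(abs(cy$Ti + cy$Te - cy$Ttot)), 1 / cfg$fs)
    expect_true(all(cy$ratio > 0 & cy$ratio < 1))
    expect_equal(cy$f_inst * cy$Ttot, rep(60, nrow(cy)), tolerance = 1e-9)
  }
})

test_that("at default noise, nearly all truth bursts are matched one-to-one", {
  matched <- total <- 0L
  for (seed in 1:5) {
    cfg <- quick_config(seed = seed)
    s <- simulate_subject(cfg, quick_protocol(60))
    b <- detect_bursts(integrate_trace(s$traces$PNA))
    tol <- 0.2 * cfg$Ti0
    hits <- vapply(s$truth$onset, function(o) any(abs(b$onset - o) <= tol),
                   logical(1))
    # one-to-one: no detected onset may claim two truth onsets
    expect_lte(nrow(b), nrow(s$truth) + 1L)
    matched <- matched + sum(hits)
    total <- total + length(hits)
  }
  expect_gte(matched / total, 0.95)
})

test_that("doubling all inter-burst gaps halves the measured frequency", {
  onsets <- seq(2, 98, by = 4)
  b1 <- data.frame(onset = onsets, peak_time = onsets + 0.5,
                   offset = onsets + 1, peak_amp = 2, baseline_amp = 0)
  b2 <- b1; b2$onset <- b1$onset * 2; b2$offset <- b1$onset * 2 + 1
  b2$peak_time <- b2$onset + 0.5
  f1 <- metric_timecourses(segment_cycles(b1, 1000))$f
  f2 <- metric_timecourses(segment_cycles(b2, 1000))$f
  expect_equal(mean(f2$value, na.rm = TRUE) / mean(f1$value, na.rm = TRUE),
               0.5, tolerance = 0.02)
})

test_that("metric time courses bin correctly and leave gaps for empty bins", {
  cy <- data.frame(t_ref = c(12, 14, 35), Ti = c(1, 1, 2), Te = c(2, 4, 2),
                   Ttot = c(3, 5, 4), ratio = c(1 / 3, 0.2, 0.5),
                   f_inst = 60 / c(3, 5, 4), amp_pna = c(1, 1, 1))
  class(cy) <- c("rb_cycles", "data.frame")
  tc <- metric_timecourses(cy, step = 10)
  # bin [10, 20): Ttot {3, 5} -> f = 60/4 = 15 under the mean-Ttot convention
  expect_equal(tc$f$value[tc$f$time == 15], 15)
  # empty bin [20, 30) is a gap, not a zero
  expect_true(is.na(tc$f$value[tc$f$time == 25]))
  # one cycle in bin [30, 40): time course equals that cycle's metrics
  expect_equal(tc$Ti$value[tc$Ti$time == 35], 2)
  expect_equal(tc$ratio$value[tc$ratio$time == 35], 0.5)
  # count-based frequency alternative
  tcc <- metric_timecourses(cy, step = 10, f_method = "count")
  expect_equal(tcc$f$value[tcc$f$time == 15], 2 * 60 / 10)
  expect_error(metric_timecourses(cy[0, ]), "at least one")
})
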