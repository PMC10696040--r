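#' Configuration for the synthetic recording generator
#'
#' Bundles the ground-truth parameters of a simulated subject: baseline
#' respiratory timing and burst amplitudes, variability, the multiunit noise
#' model, heart rate, and the multiplicative drug-effect model (peak
#' multipliers plus effect-kernel timing).
#'
#' The drug effect is multiplicative: at time `t` after an injection the
#' applied multiplier on a parameter with peak multiplier `m` is
#' `1 + w(t) * (m - 1)`, where `w` is [effect_kernel()]. A config with
#' `m_amp = m_Ti = m_Te = 1` is a null (vehicle-like) protocol.
#'
#' @param fs Sampling rate of the generated channels (Hz).
#' @param Ti0 Baseline inspiratory (phrenic burst) duration (s).
#' @param Te0 Baseline expiratory duration (s).
#' @param amp_pna0,amp_vna0 Baseline burst envelope scales (arbitrary units).
#' @param postinsp_frac Scale of the post-inspiratory VNA component relative
#'   to the inspiratory VNA component (dimensionless).
#' @param cv_cycle Cycle-to-cycle coefficient of variation of timing and
#'   amplitude draws (lognormal).
#' @param cv_subject Between-subject coefficient of variation of baseline
#'   parameters, used by [simulate_cohort()].
#' @param noise_floor Tonic (envelope-independent) noise SD (a.u.).
#' @param hr0 Baseline heart rate (beats/min).
#' @param m_amp,m_Ti,m_Te Multiplicative drug-effect factors at peak effect
#'   for burst amplitude and the two phase durations (dimensionless, > 0).
#' @param m_vna Peak multiplier for the post-inspiratory VNA component;
#'   defaults to `m_amp` when `NULL`.
#' @param t_peak Time from injection to peak effect (s).
#' @param tau_rec Recovery time constant of the effect kernel (s).
#' @param carrier If `TRUE` (default) nerve channels are envelope-modulated
#'   unit-variance Gaussian noise (multiunit emulation); if `FALSE` the
#'   envelope itself is emitted, giving a deterministic session useful for
#'   regression fixtures.
#' @param onset_frac Envelope value at burst onset as a fraction of the peak
#'   (the augmenting ramp rises from `onset_frac * amp` to `amp`).
#' @param tau_pi_frac Post-inspiratory VNA decay time constant as a fraction
#'   of `Te0`.
#' @param pi_gap Quiescent period (s) at the end of expiration during which
#'   the post-inspiratory VNA component is silent: post-inspiration is the
#'   early-expiratory phase, and the gap keeps the pre-trigger baseline span
#'   of the next burst free of the decaying tail.
#' @param ecg_jitter Coefficient of variation of R-R intervals.
#' @param seed Integer seed; the session is fully reproducible from it.
#' @return An object of class `rb_synth_config`.
#' @seealso [simulate_subject()], [simulate_cohort()], [drug_protocol()]
#' @export
synth_config <- function(fs = 1000, Ti0 = 0.9, Te0 = 3.1,
                         amp_pna0 = 1, amp_vna0 = 1, postinsp_frac = 0.5,
                         cv_cycle = 0.1, cv_subject = 0.1,
                         noise_floor = 0.02, hr0 = 320,
                         m_amp = 1, m_Ti = 1, m_Te = 1, m_vna = NULL,
                         t_peak = 120, tau_rec = 150,
                         carrier = TRUE, onset_frac = 0.25,
                         tau_pi_frac = 0.4, pi_gap = 0.6,
                         ecg_jitter = 0.02, seed = 1L) {
  if (is.null(m_vna)) m_vna <- m_amp
  cfg <- list(fs = fs, Ti0 = Ti0, Te0 = Te0, amp_pna0 = amp_pna0,
              amp_vna0 = amp_vna0, postinsp_frac = postinsp_frac,
              cv_cycle = cv_cycle, cv_subject = cv_subject,
              noise_floor = noise_floor, hr0 = hr0,
              m_amp = m_amp, m_Ti = m_Ti, m_Te = m_Te, m_vna = m_vna,
              t_peak = t_peak, tau_rec = tau_rec, carrier = isTRUE(carrier),
              onset_frac = onset_frac, tau_pi_frac = tau_pi_frac,
              pi_gap = pi_gap, ecg_jitter = ecg_jitter, seed = as.integer(seed))
  pos <- c("fs", "Ti0", "Te0", "amp_pna0", "amp_vna0", "hr0",
           "m_amp", "m_Ti", "m_Te", "m_vna", "t_peak", "tau_rec")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("`%s` must be a single positive number", f))
  nneg <- c("postinsp_frac", "cv_cycle", "cv_subject", "noise_floor",
            "ecg_jitter", "pi_gap")
  for (f in nneg)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop(sprintf("`%s` must be non-negative", f))
  if (cfg$onset_frac < 0 || cfg$onset_frac >= 1)
    stop("`onset_frac` must lie in [0, 1)")
  class(cfg) <- "rb_synth_config"
  cfg
}

#' Microinjection protocol
#'
#' Describes a simulated microinjection experiment: target site, agent, and
#' injection times on the session time axis (seconds from session start).
#' The recording spans `[0, max(injection_times) + post_duration]`; the time
#' before the first injection is the pre-injection baseline period and must
#' be at least 100 s so the 100-s baseline window fits.
#'
#' @param site Injection site label: `"BotC"`, `"preBotC"` or `"rVRG"`.
#' @param agent Agent label: `"HA"`, `"KYN"`, `"B+S"` or `"vehicle"`.
#' @param injection_times Strictly increasing injection times (s), first
#'   >= 100.
#' @param post_duration Recording time after the last injection (s).
#' @return An object of class `rb_protocol`.
#' @export
drug_protocol <- function(site = c("BotC", "preBotC", "rVRG"),
                          agent = c("HA", "KYN", "B+S", "vehicle"),
                          injection_times = 120, post_duration = 300) {
  site <- match.arg(site)
  agent <- match.arg(agent)
  injection_times <- as.numeric(injection_times)
  if (!length(injection_times) || anyNA(injection_times))
    stop("`injection_times` must be non-empty and finite")
  if (length(injection_times) > 1L && any(diff(injection_times) <= 0))
    stop("`injection_times` must be strictly increasing")
  if (injection_times[1] < 100)
    stop("pre-injection period must be >= 100 s (the 100-s baseline window must fit)")
  if (!is.numeric(post_duration) || post_duration <= 0)
    stop("`post_duration` must be positive")
  structure(list(site = site, agent = agent,
                 injection_times = injection_times,
                 pre_duration = injection_times[1],
                 post_duration = as.numeric(post_duration)),
            class = "rb_protocol")
}

#' Session duration implied by a protocol
#' @param protocol An `rb_protocol`.
#' @return Total duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "rb_protocol"))
  max(protocol$injection_times) + protocol$post_duration
}

#' Drug-effect kernel
#'
#' Temporal weight of a drug effect after an injection: zero before the
#' injection, a linear rise to 1 at `t_peak`, then exponential recovery with
#' time constant `tau_rec`. With the defaults (`t_peak` 120 s, `tau_rec`
#' 150 s) the effect peaks about 2 minutes after injection and has decayed
#' below 5% of peak by 10 minutes.
#'
#' @param t_since_injection Time since the injection (s); vectorized.
#' @param t_peak Time to peak effect (s), > 0.
#' @param tau_rec Recovery time constant (s), > 0.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' effect_kernel(c(0, 60, 120, 600), t_peak = 120, tau_rec = 150)
#' @export
effect_kernel <- function(t_since_injection, t_peak = 120, tau_rec = 150) {
  if (!is.numeric(t_peak) || length(t_peak) != 1L || t_peak <= 0)
    stop("`t_peak` must be a single positive number")
  if (!is.numeric(tau_rec) || length(tau_rec) != 1L || tau_rec <= 0)
    stop("`tau_rec` must be a single positive number")
  t <- as.numeric(t_since_injection)
  w <- numeric(length(t))
  rise <- t > 0 & t <= t_peak
  fall <- t > t_peak
  w[rise] <- t[rise] / t_peak
  w[fall] <- exp(-(t[fall] - t_peak) / tau_rec)
  w
}

#' Combined effect weight over a set of injections
#'
#' When injections overlap, the applied weight is the maximum of the
#' single-injection kernels (effects saturate rather than add).
#'
#' @param t Absolute session time(s) (s).
#' @param injection_times Injection times (s).
#' @inheritParams effect_kernel
#' @return Weight(s) in `[0, 1]`.
#' @export
effect_weight <- function(t, injection_times, t_peak = 120, tau_rec = 150) {
  w <- numeric(length(t))
  for (tj in injection_times)
    w <- pmax(w, effect_kernel(t - tj, t_peak, tau_rec))
  w
}

# lognormal draw with given mean and CV from a standard-normal deviate;
# cv = 0 returns the mean exactly (sdlog = 0)
lognormal_from_z <- function(z, mean, cv) {
  s <- sqrt(log(1 + cv^2))
  exp(log(mean) - s^2 / 2 + s * z)
}

#' Deterministic per-subject seed
#'
#' Derives stream seeds from a master seed and an index with a linear
#' congruential mix (exact in double precision), so cohorts are reproducible
#' and order-stable across versions.
#'
#' @param master Master integer seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(master, index) {
  as.integer(((as.numeric(master) %% 2^31) * 69069 + 40503 * as.numeric(index) + 12345) %% 2147483647)
}

#' Simulate one recording session
#'
#' Generates a four-channel session (PNA, VNA, ECG, PP) cycle by cycle.
#' Each respiratory cycle draws its inspiratory duration, expiratory duration
#' and burst amplitude lognormally around the current (drug-modulated)
#' targets. The PNA burst envelope is an augmenting linear ramp ending in an
#' abrupt fall; the VNA adds a decrementing exponential post-inspiratory
#' component after the phrenic offset. Nerve channels are emitted as
#' envelope-modulated Gaussian noise plus a tonic noise floor, so that
#' rectification + smoothing recovers the envelope up to the factor
#' `sqrt(2/pi)`. The ECG is a jittered R-wave train; PP is a slowly varying
#' baseline. The ground truth (per-cycle timing, amplitudes and effect
#' weights) is stored in the session.
#'
#' @param config An [synth_config()] object.
#' @param protocol An [drug_protocol()] object.
#' @param waveforms If `FALSE`, only the ground-truth cycle table is
#'   generated (no sampled channels); the truth is identical to the
#'   `waveforms = TRUE` run with the same config.
#' @param max_duration Refuse protocols longer than this many seconds.
#' @return An object of class `rb_session`: a list with elements `traces`
#'   (named list of [trace()] objects, or `NULL`), `events` (list with an
#'   `injection` [event_series()]), `protocol`, `truth` (data frame with
#'   columns `onset`, `offset`, `Ti`, `Te`, `amp_pna`, `amp_vna_pi`,
#'   `weight`) and `config`.
#' @export
simulate_subject <- function(config, protocol, waveforms = TRUE,
                             max_duration = 3600) {
  stopifnot(inherits(config, "rb_synth_config"), inherits(protocol, "rb_protocol"))
  duration <- protocol_duration(protocol)
  if (duration > max_duration)
    stop(sprintf("protocol duration %.0f s exceeds max_duration = %.0f s",
                 duration, max_duration))
  if (protocol$pre_duration < 100)
    stop("pre-injection period must be >= 100 s")

  set.seed(config$seed)
  inj <- protocol$injection_times

  # pre-draw per-cycle deviates so the truth table is identical whether or
  # not waveforms are synthesized
  ttot_floor <- 0.2 * (config$Ti0 * min(1, config$m_Ti) +
                       config$Te0 * min(1, config$m_Te))
  n_max <- ceiling(duration / ttot_floor) + 20L
  z_ti <- stats::rnorm(n_max); z_te <- stats::rnorm(n_max); z_amp <- stats::rnorm(n_max)

  onset <- numeric(0); Ti <- numeric(0); Te <- numeric(0)
  amp_pna <- numeric(0); amp_vna <- numeric(0); amp_vna_pi <- numeric(0)
  weight <- numeric(0)
  t_on <- 0.5; k <- 0L
  while (k < n_max) {
    k <- k + 1L
    w <- effect_weight(t_on, inj, config$t_peak, config$tau_rec)
    ti_k <- lognormal_from_z(z_ti[k], config$Ti0 * (1 + w * (config$m_Ti - 1)),
                             config$cv_cycle)
    te_k <- lognormal_from_z(z_te[k], config$Te0 * (1 + w * (config$m_Te - 1)),
                             config$cv_cycle)
    a_fac <- lognormal_from_z(z_amp[k], 1, config$cv_cycle)
    if (t_on + ti_k + te_k > duration) break
    onset <- c(onset, t_on); Ti <- c(Ti, ti_k); Te <- c(Te, te_k)
    amp_pna <- c(amp_pna, config$amp_pna0 * (1 + w * (config$m_amp - 1)) * a_fac)
    amp_vna <- c(amp_vna, config$amp_vna0 * (1 + w * (config$m_amp - 1)) * a_fac)
    amp_vna_pi <- c(amp_vna_pi,
                    config$postinsp_frac * config$amp_vna0 *
                      (1 + w * (config$m_vna - 1)) * a_fac)
    weight <- c(weight, w)
    t_on <- t_on + ti_k + te_k
  }
  truth <- data.frame(onset = onset, offset = onset + Ti, Ti = Ti, Te = Te,
                      amp_pna = amp_pna, amp_vna_pi = amp_vna_pi,
                      weight = weight)

  # R-wave times (drawn in both modes so the stream layout is stable)
  rr0 <- 60 / config$hr0
  n_beats <- ceiling(duration / (rr0 * 0.5)) + 10L
  rr <- rr0 * (1 + config$ecg_jitter * stats::rnorm(n_beats))
  rr <- pmax(rr, 0.3 * rr0)
  r_times <- 0.2 + cumsum(rr)
  r_times <- r_times[r_times < duration - 0.05]

  traces <- NULL
  if (waveforms) {
    fs <- config$fs
    n <- round(duration * fs)
    tt <- (seq_len(n) - 1L) / fs

    env_pna <- numeric(n); env_vna <- numeric(n)
    for (j in seq_along(onset)) {
      i_on <- round(onset[j] * fs) + 1L
      i_off <- max(i_on, round((onset[j] + Ti[j]) * fs))
      idx <- i_on:i_off
      ramp <- config$onset_frac +
        (1 - config$onset_frac) * (idx - i_on) / max(1L, i_off - i_on)
      env_pna[idx] <- amp_pna[j] * ramp
      env_vna[idx] <- amp_vna[j] * ramp
      # post-inspiratory VNA component: decrementing exponential confined to
      # early expiration (quiescent for pi_gap seconds before the next onset)
      i_pi_end <- min(n, round((onset[j] + Ti[j] +
                                max(0, Te[j] - config$pi_gap)) * fs))
      if (i_pi_end > i_off) {
        pidx <- (i_off + 1L):i_pi_end
        env_vna[pidx] <- env_vna[pidx] + amp_vna_pi[j] *
          exp(-((pidx - 1) / fs - (onset[j] + Ti[j])) / (config$tau_pi_frac * config$Te0))
      }
    }

    mk_nerve <- function(env) {
      x <- if (config$carrier) env * stats::rnorm(n) else env
      if (config$noise_floor > 0) x <- x + config$noise_floor * stats::rnorm(n)
      x
    }
    pna <- mk_nerve(env_pna)
    vna <- mk_nerve(env_vna)

    ecg <- numeric(n)
    half <- round(0.016 * fs)
    for (tr in r_times) {
      ic <- round(tr * fs) + 1L
      idx <- max(1L, ic - half):min(n, ic + half)
      ecg[idx] <- ecg[idx] + exp(-0.5 * ((idx - ic) / (0.004 * fs))^2)
    }
    if (config$carrier && config$noise_floor > 0)
      ecg <- ecg + config$noise_floor * stats::rnorm(n)

    pp <- 70 + 3 * sin(2 * pi * tt / 37)

    traces <- list(
      PNA = trace(pna, fs, "PNA"),
      VNA = trace(vna, fs, "VNA"),
      ECG = trace(ecg, fs, "ECG"),
      PP  = trace(pp,  fs, "PP"))
    attr(traces$PNA, "envelope") <- env_pna
    attr(traces$VNA, "envelope") <- env_vna
  }

  structure(list(traces = traces,
                 events = list(injection = event_series(inj, "injection")),
                 protocol = protocol, truth = truth, config = config),
            class = "rb_session")
}

#' @export
print.rb_session <- function(x, ...) {
  cat(sprintf("<rb_session> %s @ %s, %d injections, %d truth cycles%s\n",
              x$protocol$agent, x$protocol$site,
              length(x$protocol$injection_times), nrow(x$truth),
              if (is.null(x$traces)) " (truth only)" else
                sprintf(", %d channels at %g Hz", length(x$traces),
                        x$traces[[1]]$fs)))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Runs [simulate_subject()] once per subject. Each subject's baseline
#' parameters (`Ti0`, `Te0`, amplitude scales, `hr0`) are jittered
#' lognormally with CV `cv_subject`; jitter and simulation use separate
#' seeds derived deterministically from the master seed, so the cohort is
#' reproducible and order-stable.
#'
#' @param n Number of subjects (>= 1).
#' @inheritParams simulate_subject
#' @return A list of `rb_session` objects of length `n`.
#' @export
simulate_cohort <- function(n, config, protocol, waveforms = TRUE,
                            max_duration = 3600) {
  stopifnot(inherits(config, "rb_synth_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1")
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    set.seed(subject_seed(config$seed, 2L * i))
    z <- stats::rnorm(5)
    cfg <- config
    cfg$Ti0      <- lognormal_from_z(z[1], config$Ti0, config$cv_subject)
    cfg$Te0      <- lognormal_from_z(z[2], config$Te0, config$cv_subject)
    cfg$amp_pna0 <- lognormal_from_z(z[3], config$amp_pna0, config$cv_subject)
    cfg$amp_vna0 <- lognormal_from_z(z[4], config$amp_vna0, config$cv_subject)
    cfg$hr0      <- lognormal_from_z(z[5], config$hr0, config$cv_subject)
    cfg$seed <- subject_seed(config$seed, 2L * i + 1L)
    simulate_subject(cfg, protocol, waveforms = waveforms,
                     max_duration = max_duration)
  })
}
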