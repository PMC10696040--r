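#' Expected response directions implied by a generator config
#'
#' Given the peak multipliers of a synthetic config, derives the direction
#' (`"up"`, `"down"`, `"none"`) that each pipeline metric should show at
#' peak effect. Phase durations and amplitudes follow their multipliers
#' directly; frequency and the inspiratory ratio are derived from the
#' timing multipliers:
#' `f` scales as `(Ti0 + Te0) / (m_Ti * Ti0 + m_Te * Te0)` and `ratio` as
#' `m_Ti * (Ti0 + Te0) / (m_Ti * Ti0 + m_Te * Te0)`.
#'
#' @param config An [synth_config()].
#' @return Named character vector over
#'   `c("amp_PNA", "amp_postinsp_VNA", "f", "Ti", "Te", "ratio")`.
#' @export
expected_directions <- function(config) {
  stopifnot(inherits(config, "rb_synth_config"))
  ttot0 <- config$Ti0 + config$Te0
  ttot1 <- config$m_Ti * config$Ti0 + config$m_Te * config$Te0
  fac <- c(amp_PNA = config$m_amp,
           amp_postinsp_VNA = config$m_vna,
           f = ttot0 / ttot1,
           Ti = config$m_Ti,
           Te = config$m_Te,
           ratio = config$m_Ti * ttot0 / ttot1)
  dir <- ifelse(fac > 1 + 1e-9, "up", ifelse(fac < 1 - 1e-9, "down", "none"))
  stats::setNames(dir, names(fac))
}

#' Site-by-agent direction-regression fixtures
#'
#' Nine noise-free generator configurations, one per combination of
#' injection site (BotC, preBotC, rVRG) and agent (HA, KYN, B+S), whose
#' peak multipliers encode the qualitative response directions of the
#' corresponding microinjection experiments: e.g. expiratory shortening
#' with increased frequency and ratio for HA at the BotC, proportional
#' shortening of both phases (frequency up, ratio unchanged) for HA at the
#' preBotC, and expiratory lengthening with decreased frequency for HA at
#' the rVRG. The configs are deterministic (no cycle variability, no
#' carrier noise), so each fixture's recovered directions are an exact
#' regression surface for the pipeline.
#'
#' @param fs Sampling rate for the fixture sessions (Hz).
#' @param seed Master seed stored in each config.
#' @return A list of nine elements, each with `site`, `agent`, `config`
#'   (an [synth_config()]) and `expected` (from [expected_directions()]).
#' @export
direction_fixtures <- function(fs = 400, seed = 1L) {
  spec <- list(
    list(site = "BotC",    agent = "HA",  m_amp = 0.80, m_Ti = 1.00, m_Te = 0.70, m_vna = 0.80),
    list(site = "BotC",    agent = "KYN", m_amp = 0.80, m_Ti = 1.00, m_Te = 0.70, m_vna = 0.80),
    list(site = "BotC",    agent = "B+S", m_amp = 0.80, m_Ti = 1.00, m_Te = 1.00, m_vna = 1.00),
    list(site = "preBotC", agent = "HA",  m_amp = 0.80, m_Ti = 0.80, m_Te = 0.80, m_vna = 0.80),
    list(site = "preBotC", agent = "KYN", m_amp = 0.80, m_Ti = 0.80, m_Te = 0.80, m_vna = 0.80),
    list(site = "preBotC", agent = "B+S", m_amp = 0.80, m_Ti = 1.00, m_Te = 1.00, m_vna = 1.00),
    list(site = "rVRG",    agent = "HA",  m_amp = 0.80, m_Ti = 1.00, m_Te = 1.30, m_vna = 0.80),
    list(site = "rVRG",    agent = "KYN", m_amp = 0.80, m_Ti = 1.00, m_Te = 1.00, m_vna = 0.80),
    list(site = "rVRG",    agent = "B+S", m_amp = 0.80, m_Ti = 1.00, m_Te = 0.70, m_vna = 1.00))
  lapply(spec, function(s) {
    cfg <- synth_config(fs = fs, cv_cycle = 0, cv_subject = 0,
                        noise_floor = 0, carrier = FALSE,
                        m_amp = s$m_amp, m_Ti = s$m_Ti, m_Te = s$m_Te,
                        m_vna = s$m_vna, seed = seed)
    list(site = s$site, agent = s$agent, config = cfg,
         expected = expected_directions(cfg))
  })
}

#' Recovered response directions from a group result
#'
#' Converts group one-sample t-tests of change rates into direction calls:
#' `"none"` when `p >= 0.05`, otherwise `"up"`/`"down"` by the sign of the
#' mean change relative to 100%.
#'
#' @param group An `rb_group_result` from [run_pipeline()] /
#'   [group_response()].
#' @param metrics Which metrics to call.
#' @return Named character vector of directions.
#' @export
recovered_directions <- function(group,
                                 metrics = c("amp_PNA", "amp_postinsp_VNA",
                                             "f", "Ti", "Te", "ratio")) {
  stopifnot(inherits(group, "rb_group_result"))
  vapply(metrics, function(m) {
    s <- group$tests[[m]]
    if (is.null(s) || !is.finite(s$mean)) return(NA_character_)
    if (!s$significant) "none" else if (s$mean > 100) "up" else "down"
  }, character(1))
}
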