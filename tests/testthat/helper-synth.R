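# Small, fast generator settings shared across tests. Sessions are scaled
# down (lower sampling rate, short post-injection period) so the suite runs
# quickly; the defaults of synth_config() are not touched.

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(fs = 400, seed = 1L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

quick_protocol <- function(post_duration = 120, injection_times = 120,
                           site = "BotC", agent = "vehicle") {
  drug_protocol(site, agent, injection_times = injection_times,
                post_duration = post_duration)
}

# a deterministic (noise-free, envelope-only) config for exact checks
clean_config <- function(...) {
  quick_config(cv_cycle = 0, cv_subject = 0, noise_floor = 0,
               carrier = FALSE, ...)
}
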