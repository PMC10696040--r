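#' Respiratory cycles from the generator's ground truth
#'
#' Builds the same per-cycle table as [segment_cycles()], but from the
#' ground-truth burst times stored in a synthetic session instead of from
#' detection. Useful for validating the detection chain and for
#' statistics-level simulation studies where the waveform stage is not the
#' question.
#'
#' @param session An `rb_session` from [simulate_subject()].
#' @param convention Same as in [segment_cycles()].
#' @return An `rb_cycles` data frame with the additional column
#'   `amp_vna_pi`.
#' @export
truth_cycles <- function(session, convention = c("terminating", "opening")) {
  convention <- match.arg(convention)
  stopifnot(inherits(session, "rb_session"))
  tr <- session$truth
  nb <- nrow(tr)
  if (nb < 2L) stop("truth table has fewer than 2 cycles")
  k <- seq_len(nb - 1L)
  src <- if (convention == "terminating") k + 1L else k
  ttot <- tr$offset[k + 1L] - tr$offset[k]
  out <- data.frame(t_ref = tr$offset[k + 1L], Ti = tr$Ti[src],
                    Te = ttot - tr$Ti[src], Ttot = ttot,
                    ratio = tr$Ti[src] / ttot, f_inst = 60 / ttot,
                    amp_pna = tr$amp_pna[src], amp_vna_pi = tr$amp_vna_pi[src])
  class(out) <- c("rb_cycles", "data.frame")
  attr(out, "excluded") <- 0L
  out
}

#' Per-cycle amplitude binned on the common grid
#'
#' Bins a per-cycle amplitude column of an `rb_cycles` table into the
#' 10-s grid, mirroring [metric_timecourses()] for amplitudes measured per
#' cycle (e.g. ground-truth amplitudes) rather than from triggered
#' averages.
#'
#' @param cycles An `rb_cycles` data frame.
#' @param column Amplitude column name (default `"amp_pna"`).
#' @param metric Metric label for the result.
#' @param step Grid step (s).
#' @param t_range Optional time range to cover.
#' @return A [metric_timecourse()].
#' @export
cycle_amplitude_timecourse <- function(cycles, column = "amp_pna",
                                       metric = "amp_PNA", step = 10,
                                       t_range = NULL) {
  stopifnot(is.data.frame(cycles), column %in% names(cycles))
  b <- bin_mean(cycles$t_ref, cycles[[column]], step, t_range)
  metric_timecourse(b$time, b$value, metric, step)
}
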