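# Independent brute-force oracles used to validate the fast implementations.

# per-sample windowed mean of |x| with a centered, shrinking window
brute_integrate <- function(x, fs, window) {
  L <- round(window * fs)
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(abs(x[max(1L, i - left):min(n, i + right)])), numeric(1))
}

# stack-and-mean triggered average for one window of triggers
brute_stack_mean <- function(samples, fs, t0, trig_times, lag) {
  il <- round(lag[1] * fs):round(lag[2] * fs)
  segs <- lapply(trig_times, function(tt) {
    i0 <- round((tt - t0) * fs) + 1L
    idx <- i0 + il
    if (idx[1] < 1L || idx[length(idx)] > length(samples)) return(NULL)
    samples[idx]
  })
  segs <- Filter(Negate(is.null), segs)
  if (!length(segs)) return(NULL)
  Reduce(`+`, segs) / length(segs)
}
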