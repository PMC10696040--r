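#' Normalize a metric time course to percent of baseline
#'
#' The baseline is the mean of the metric over the `baseline_dur` seconds
#' preceding the injection (100 s by default); that mean is defined as 100%
#' and every bin is expressed relative to it. Gaps propagate.
#'
#' @param tc A [metric_timecourse()].
#' @param injection_time Injection time (s) on the session axis.
#' @param baseline_dur Baseline window length (s), default 100.
#' @return The time course with a `percent` column added.
#' @export
percent_of_baseline <- function(tc, injection_time, baseline_dur = 100) {
  stopifnot(inherits(tc, "rb_timecourse"))
  if (!is.numeric(baseline_dur) || baseline_dur <= 0)
    stop("`baseline_dur` must be positive")
  sel <- tc$time %inco% c(injection_time - baseline_dur, injection_time)
  vals <- tc$value[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no non-missing values in the baseline window")
  base <- mean(vals)
  if (base == 0) stop("baseline mean is zero; cannot normalize")
  tc$percent <- 100 * tc$value / base
  attr(tc, "baseline_mean") <- base
  attr(tc, "injection_time") <- injection_time
  attr(tc, "baseline_dur") <- baseline_dur
  tc
}

#' Change rate of a percent-normalized time course
#'
#' The change rate is the mean percent-of-baseline value over a
#' post-injection analysis window (the "gray area" of a time-course panel).
#' The default window `[60, 180)` s after injection brackets the
#' effect peak at about 2 minutes; experiments may narrow it (e.g.
#' `c(90, 150)`) to sit closer to the peak.
#'
#' @param tc A percent-normalized [metric_timecourse()] (see
#'   [percent_of_baseline()]).
#' @param window Two-element analysis window (s) relative to the injection,
#'   half-open.
#' @param injection_time Injection time (s); defaults to the one recorded by
#'   [percent_of_baseline()].
#' @return The mean percent over the window (scalar, %).
#' @export
change_rate <- function(tc, window = c(60, 180),
                        injection_time = attr(tc, "injection_time")) {
  stopifnot(inherits(tc, "rb_timecourse"))
  if (is.null(tc$percent)) stop("`tc` has no percent column; normalize first")
  if (is.null(injection_time)) stop("`injection_time` is unknown")
  if (length(window) != 2L || window[2] <= window[1] || window[1] < 0)
    stop("`window` must be an increasing post-injection interval")
  sel <- (tc$time - injection_time) %inco% window
  vals <- tc$percent[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no non-missing samples in the analysis window")
  mean(vals)
}

new_group_stats <- function(metric, n, mean, sem, statistic, df, p, test,
                            degenerate = FALSE) {
  structure(list(metric = metric, n = n, mean = mean, sem = sem,
                 statistic = statistic, df = df, p = p, test = test,
                 significant = is.finite(p) && p < 0.05,
                 degenerate = degenerate),
            class = "rb_group_stats")
}

#' @export
print.rb_group_stats <- function(x, ...) {
  cat(sprintf("<rb_group_stats> %s%s: n=%d, mean=%.3f, sem=%.3f, t=%.4g (df=%g), p=%.4g%s%s\n",
              x$test, if (!is.na(x$metric)) paste0(" [", x$metric, "]") else "",
              x$n, x$mean, x$sem, x$statistic, x$df, x$p,
              if (x$significant) " *" else "",
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' One-sample t-test against a reference value
#'
#' Two-sided one-sample t-test, typically of change rates against 100%
#' (no change). Zero-variance inputs are handled explicitly: if all values
#' equal `mu0` the result is `t = 0, p = 1`; if all values equal some other
#' constant the statistic is infinite and `p` is reported as 0 with a
#' `degenerate` flag. Exactly constant samples only arise from noise-free
#' synthetic input, where sub-percent offsets from the reference are
#' timing-resolution artifacts of the measurement chain, so the equality
#' check uses a 1% relative tolerance — two orders of magnitude below the
#' smallest effects the pipeline is used to detect.
#'
#' @param values Numeric vector, `n >= 2`, finite.
#' @param mu0 Null value (default 100).
#' @param metric Optional metric label carried into the result.
#' @return An `rb_group_stats` object with fields `n`, `mean`, `sem`
#'   (sd/sqrt(n)), `statistic`, `df`, `p`, `significant` (p < 0.05).
#' @export
one_sample_t <- function(values, mu0 = 100, metric = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  sem <- s / sqrt(n)
  if (s == 0) {
    # zero variance: equal to mu0 within measurement resolution is "no change"
    if (abs(m - mu0) <= 1e-2 * max(1, abs(mu0)))
      return(new_group_stats(metric, n, m, 0, 0, n - 1L, 1,
                             "one-sample t", degenerate = TRUE))
    return(new_group_stats(metric, n, m, 0, sign(m - mu0) * Inf, n - 1L, 0,
                           "one-sample t", degenerate = TRUE))
  }
  t <- (m - mu0) / sem
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  new_group_stats(metric, n, m, sem, t, n - 1L, p, "one-sample t")
}

#' Paired t-test
#'
#' One-sample t-test of the pairwise differences (`after - before`)
#' against zero, used e.g. to contrast an agent's effect with and without a
#' blocker in the same subjects.
#'
#' @param before,after Equal-length numeric vectors.
#' @param metric Optional metric label.
#' @return An `rb_group_stats` object (mean/sem describe the differences).
#' @export
paired_t <- function(before, after, metric = NA_character_) {
  if (length(before) != length(after))
    stop("`before` and `after` must have equal length")
  out <- one_sample_t(after - before, mu0 = 0, metric = metric)
  out$test <- "paired t"
  out
}

# Golub-Welsch nodes/weights for Gauss-Hermite (weight exp(-x^2)) and
# Gauss-Legendre on (0, 1)
gauss_hermite <- function(n) {
  b <- sqrt(seq_len(n - 1L) / 2)
  J <- diag(0, n); J[cbind(1:(n - 1L), 2:n)] <- b; J[cbind(2:n, 1:(n - 1L))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

gauss_legendre01 <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n); J[cbind(1:(n - 1L), 2:n)] <- b; J[cbind(2:n, 1:(n - 1L))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

.rb_quad <- new.env(parent = emptyenv())

pdunnett_quad <- function() {
  if (is.null(.rb_quad$gh)) {
    .rb_quad$gh <- gauss_hermite(48L)
    .rb_quad$gl <- gauss_legendre01(64L)
  }
  .rb_quad
}

#' Two-sided Dunnett distribution (balanced many-to-one)
#'
#' `P(max_j |T_j| <= q)` for `k` comparisons against a common control in a
#' balanced design, where the `T_j` are equicorrelated multivariate t
#' (pairwise correlation 1/2) with `df` error degrees of freedom. Evaluated
#' by deterministic two-dimensional Gauss quadrature using the
#' common-factor representation of the equicorrelated normal, so repeated
#' calls are exactly reproducible.
#'
#' @param q Non-negative quantile (vectorized).
#' @param k Number of comparisons (>= 1).
#' @param df Error degrees of freedom (> 0).
#' @return Probabilities in `[0, 1]`.
#' @export
pdunnett_abs <- function(q, k, df) {
  stopifnot(k >= 1, df > 0)
  qd <- pdunnett_quad()
  gh <- qd$gh
  gl <- qd$gl
  wn <- sqrt(2) * gh$x           # w ~ N(0,1) nodes
  ww <- gh$w / sqrt(pi)
  ss <- sqrt(stats::qchisq(gl$x, df) / df)  # s ~ chi_df/sqrt(df) via prob. transform
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    if (qi <= 0) return(0)
    a <- sqrt(2) * qi * ss       # one per s-node
    inner <- vapply(seq_along(ss), function(j) {
      g <- (stats::pnorm(a[j] - wn) - stats::pnorm(-a[j] - wn))^k
      sum(ww * g)
    }, numeric(1))
    min(1, max(0, sum(gl$w * inner)))
  }, numeric(1))
}

#' Repeated-measures ANOVA with Dunnett many-to-one comparisons
#'
#' One-way repeated-measures ANOVA across timepoints, followed by Dunnett
#' comparisons of every timepoint against the control timepoint using the
#' within-subject error term. Subjects with any missing timepoint are
#' dropped listwise (and counted in the result). Adjusted p-values come
#' from [pdunnett_abs()], the exact balanced two-sided Dunnett
#' distribution.
#'
#' @param mat Numeric matrix, subjects in rows, timepoints in columns
#'   (typically percent-of-baseline values on the 10-s grid).
#' @param control Column index of the control timepoint (default 1, e.g.
#'   the last pre-injection bin).
#' @return A list of class `rb_rm_dunnett` with elements `anova`
#'   (`F`, `df1`, `df2`, `p`), `dunnett` (data frame: `timepoint`, `diff`,
#'   `t`, `p_adj`, `significant`), `n_subjects`, `n_dropped`,
#'   `control`.
#' @export
rm_anova_dunnett <- function(mat, control = 1L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 timepoints")
  if (control < 1L || control > ncol(mat)) stop("invalid control index")
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  S <- nrow(mat); Tn <- ncol(mat)
  if (S < 2L) stop("need at least 2 complete subjects")
  tp_names <- colnames(mat)
  if (is.null(tp_names)) tp_names <- as.character(seq_len(Tn))

  df_long <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(S), times = Tn)),
    time = factor(rep(seq_len(Tn), each = S)))
  fit <- stats::aov(y ~ time + Error(subject), data = df_long)
  within <- summary(fit)[["Error: Within"]][[1]]
  F_val <- within["time", "F value"]
  p_val <- within["time", "Pr(>F)"]
  df1 <- within["time", "Df"]
  df2 <- within["Residuals", "Df"]
  mse <- within["Residuals", "Mean Sq"]
  # guard against zero within-subject variance (up to floating noise)
  scale2 <- mean((mat - mean(mat))^2)
  if (mse <= 1e-24 * max(scale2, 1e-300)) mse <- 0
  if (mse == 0 || !is.finite(F_val)) {
    F_val <- if (within["time", "Mean Sq"] > 1e-24 * max(scale2, 1e-300)) Inf else 0
    p_val <- if (F_val > 0) 0 else 1
  }

  others <- setdiff(seq_len(Tn), control)
  means <- colMeans(mat)
  diffs <- means[others] - means[control]
  se <- sqrt(2 * mse / S)
  tol_d <- 1e-8 * max(1, abs(means[control]))
  tstat <- if (se > 0) diffs / se else
    ifelse(abs(diffs) <= tol_d, 0, sign(diffs) * Inf)
  kk <- length(others)
  p_adj <- vapply(tstat, function(tv) {
    if (!is.finite(tv)) return(if (tv == 0) 1 else 0)
    1 - pdunnett_abs(abs(tv), kk, df2)
  }, numeric(1))

  structure(list(
    anova = list(F = F_val, df1 = df1, df2 = df2, p = p_val),
    dunnett = data.frame(timepoint = tp_names[others], diff = unname(diffs),
                         t = unname(tstat), p_adj = unname(p_adj),
                         significant = unname(p_adj < 0.05)),
    n_subjects = S, n_dropped = n_dropped, control = tp_names[control]),
    class = "rb_rm_dunnett")
}

#' @export
print.rb_rm_dunnett <- function(x, ...) {
  cat(sprintf("<rb_rm_dunnett> RM-ANOVA F(%g, %g) = %.4g, p = %.4g; control = %s; n = %d (%d dropped)\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p,
              x$control, x$n_subjects, x$n_dropped))
  print(x$dunnett, row.names = FALSE)
  invisible(x)
}
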