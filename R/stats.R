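# Group-level aggregation, normality assessment, TOST equivalence testing
# and power-based sample-size computation.
#
# Conventions (matching the summary-table layer): summary tables use the
# population standard deviation (divisor n) and the population-spread
# interval mean +/- 1.96 sd; inferential statistics (TOST) use the sample
# standard deviation (divisor n - 1) inside the standard error.

#' Aggregate per-subject bone means into a group summary row
#'
#' @param means numeric vector of per-subject (or per-scan) mean surface
#'   distances (mm), n >= 2.
#' @param label optional group label.
#' @return a `bone_summary` row (see [summarize_bone()]) plus formatted
#'   columns `mean_fmt`, `sd_fmt`, `lower_fmt`, `upper_fmt` following the
#'   report formatting rule of [fmt_mm()].
#' @export
aggregate_group <- function(means, label = NULL) {
  means <- as.numeric(means)
  if (length(means) < 2L) stop("need at least 2 values")
  out <- summarize_bone(means, bone = label)
  out$mean_fmt <- fmt_mm(out$mean)
  out$sd_fmt <- fmt_mm(out$sd)
  out$lower_fmt <- fmt_mm(out$lower)
  out$upper_fmt <- fmt_mm(out$upper)
  out
}

#' Shapiro-Wilk normality test
#'
#' Royston's AS R94 algorithm (via [stats::shapiro.test()]).
#'
#' @param x numeric vector, 3 <= n <= 5000, not all equal.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L) stop("n must be in [3, 5000]")
  if (diff(range(x)) == 0) stop("all values are identical")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

# asymptotic two-sided Kolmogorov distribution: P(sqrt(n) D > q)
kolmogorov_sf <- function(q) {
  if (q <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * q^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov test against a fitted normal
#'
#' D is the supremum over the sample of the distance between the empirical
#' CDF (evaluated at and just before each order statistic) and the normal
#' CDF with the sample mean and sample (n - 1) standard deviation. The
#' p-value uses the asymptotic Kolmogorov distribution without correction
#' for the estimated parameters (anti-conservative; reported for
#' comparability with common practice).
#'
#' @param x numeric vector, n >= 2, not all equal.
#' @return list with `D` and `p`.
#' @export
ks_normal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  if (diff(range(x)) == 0) stop("all values are identical")
  xs <- sort(x)
  Fh <- pnorm(xs, mean(x), sd(x))
  i <- seq_len(n)
  D <- max(i / n - Fh, Fh - (i - 1) / n)
  list(D = D, p = kolmogorov_sf(sqrt(n) * D))
}

#' One-sample TOST equivalence test
#'
#' Two one-sided t tests of the mean against -margin and +margin.
#' Equivalence is declared when both one-sided tests reject at level
#' `alpha`, equivalently when the two-sided 1 - 2 alpha confidence
#' interval lies entirely inside (-margin, margin).
#'
#' @param x numeric vector (mm), n >= 3, positive variance.
#' @param margin equivalence margin Delta in mm (default 0.15, half the
#'   smallest voxel dimension of the emulated protocols).
#' @param alpha one-sided level (default 0.05).
#' @return an `equivalence_result`: list with `n`, `mean`, `sd`, `se`,
#'   `margin`, `alpha`, `p_lower`, `p_upper`, `ci_lower`, `ci_upper`
#'   (1 - 2 alpha interval), `equivalent`.
#' @export
tost_one_sample <- function(x, margin = 0.15, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 values")
  s <- sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  if (margin <= 0) stop("margin must be > 0")
  m <- mean(x)
  se <- s / sqrt(n)
  df <- n - 1
  t_lower <- (m + margin) / se   # H0: mu <= -margin, reject for large t
  t_upper <- (m - margin) / se   # H0: mu >= +margin, reject for small t
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df)
  tcrit <- qt(1 - alpha, df)
  ci <- m + c(-1, 1) * tcrit * se
  res <- list(n = n, mean = m, sd = s, se = se, margin = margin,
              alpha = alpha, p_lower = p_lower, p_upper = p_upper,
              ci_lower = ci[1], ci_upper = ci[2],
              equivalent = max(p_lower, p_upper) < alpha)
  stopifnot(res$equivalent == (ci[1] > -margin && ci[2] < margin))
  class(res) <- "equivalence_result"
  res
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat("One-sample TOST: mean ", fmt_mm(x$mean), " mm (n = ", x$n,
      "), margin +/-", format(x$margin), " mm\n",
      "  p(lower) = ", format(x$p_lower, digits = 3),
      ", p(upper) = ", format(x$p_upper, digits = 3), "\n",
      "  ", round((1 - 2 * x$alpha) * 100), "% CI [", fmt_mm(x$ci_lower),
      ", ", fmt_mm(x$ci_upper), "] mm -> ",
      if (x$equivalent) "equivalent" else "not shown equivalent", "\n",
      sep = "")
  invisible(x)
}

# power of the two-sided one-sample t test at effect size d and size n,
# from the noncentral t distribution with noncentrality d * sqrt(n)
t_test_power <- function(d, n, alpha) {
  df <- n - 1
  ncp <- d * sqrt(n)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Minimum sample size from a power analysis
#'
#' Smallest n >= 2 such that a two-sided one-sample t test at level
#' `alpha` reaches the target power for standardized effect size `d`
#' (Cohen's d), with power computed from the noncentral t distribution.
#'
#' @param d effect size (Cohen's d, nonzero).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param n_max search bound.
#' @return minimum integer n.
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (d == 0) stop("effect size must be nonzero")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  d <- abs(d)
  n <- 2L
  while (n <= n_max) {
    if (t_test_power(d, n, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("target power not reachable within n_max samples")
}

#' Normal quantile-quantile points
#'
#' Ordered sample values against standard-normal quantiles at plotting
#' positions (i - 0.5) / n, plus the reference line (slope = sample sd,
#' intercept = sample mean) that maps the identity after standardization.
#'
#' @param x numeric vector, n >= 2.
#' @return list with `theoretical`, `sample`, `slope`, `intercept`.
#' @export
qq_points <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  list(theoretical = qnorm((seq_len(n) - 0.5) / n), sample = sort(x),
       slope = sd(x), intercept = mean(x))
}
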