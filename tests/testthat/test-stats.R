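# Statistics layer: group aggregation, normality tests, TOST, power.

test_that("aggregate_group reproduces the summary-table conventions", {
  # patient femur row: means of the four per-scan values
  g <- aggregate_group(c(0.01, 0.11, 0.003, -0.10))
  expect_identical(g$mean_fmt, "0.006")
  expect_identical(g$sd_fmt, "0.07")
  expect_identical(g$upper_fmt, "0.15")
  expect_identical(g$lower_fmt, "-0.14")
  cst <- aggregate_group(rep(0.2, 5))
  expect_equal(cst$sd, 0)
  expect_equal(c(cst$lower, cst$upper), c(0.2, 0.2))
  pm <- aggregate_group(c(-1, 1))
  expect_equal(pm$mean, 0)
  expect_equal(pm$sd, 1)
  expect_equal(c(pm$lower, pm$upper), c(-1.96, 1.96))
  expect_error(aggregate_group(1), "at least 2")
})

test_that("report formatting extends precision for near-zero values", {
  expect_identical(fmt_mm(c(0.00575, 0.003, -0.0004, -0.036, 0.128)),
                   c("0.006", "0.003", "-0.0004", "-0.04", "0.13"))
})

test_that("shapiro_wilk matches an independent AS R94 implementation", {
  set.seed(123)
  x <- rnorm(20)
  sw <- shapiro_wilk(x)
  # reference value from an independent implementation of Royston's
  # algorithm, frozen for this exact seeded sample
  expect_equal(sw$W, 0.968584231602, tolerance = 1e-6)
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
  expect_error(shapiro_wilk(c(1, 2)), "n must be")
})

test_that("ks_normal matches brute-force enumeration and construction bounds", {
  # x = {-1, +1}: fitted mean 0, s = sqrt(2); sup over the four candidate
  # ECDF gaps, enumerated directly
  ks <- ks_normal(c(-1, 1))
  Fh <- pnorm(c(-1, 1), 0, sqrt(2))
  cand <- c(0.5 - Fh[1], Fh[1] - 0, 1 - Fh[2], Fh[2] - 0.5)
  expect_equal(ks$D, max(cand), tolerance = 1e-12)
  expect_equal(ks$D, 0.2602499389, tolerance = 1e-9)
  # exact fitted-normal quantiles at (i - 0.5)/n sit within 0.5/n of the CDF
  n <- 100
  xq <- qnorm((seq_len(n) - 0.5) / n)
  xq <- (xq - mean(xq)) / sd(xq) # make the fitted parameters exact
  expect_lte(ks_normal(xq)$D, 0.5 / n + 0.002)
  expect_error(ks_normal(rep(2, 5)), "identical")
})

test_that("ks_normal agrees with ks.test on tie-free samples", {
  set.seed(77)
  x <- rnorm(40, 0.1, 0.8)
  ks <- ks_normal(x)
  ref <- stats::ks.test(x, "pnorm", mean(x), sd(x), exact = FALSE)
  expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$p, ref$p.value, tolerance = 1e-9)
})

test_that("TOST declares equivalence in the huge-margin limit", {
  set.seed(5)
  x <- rnorm(30, 0, 1)
  x <- x - mean(x) # exactly centred
  r <- tost_one_sample(x, margin = 1e6)
  expect_true(r$equivalent)
  expect_lt(r$p_lower, 1e-12)
  expect_lt(r$p_upper, 1e-12)
  expect_error(tost_one_sample(rep(1, 5)), "zero variance")
  expect_error(tost_one_sample(x[1:2]), "at least 3")
})

test_that("TOST p-rule, CI-rule and one-sided rejections coincide on 1000 samples", {
  set.seed(1234)
  n <- 56
  agree <- logical(1000)
  for (i in seq_len(1000)) {
    x <- rnorm(n, mean = runif(1, -0.2, 0.2), sd = runif(1, 0.05, 0.3))
    r <- tost_one_sample(x, margin = 0.15, alpha = 0.05)
    # independent CI-inclusion oracle from t.test's 90% interval
    ci <- stats::t.test(x, conf.level = 0.90)$conf.int
    dec_ci <- ci[1] > -0.15 && ci[2] < 0.15
    dec_p <- max(r$p_lower, r$p_upper) < 0.05
    both <- (r$p_lower < 0.05) && (r$p_upper < 0.05)
    agree[i] <- (r$equivalent == dec_ci) && (dec_ci == dec_p) && (dec_p == both)
  }
  expect_true(all(agree))
})

test_that("power_sample_size matches a quadrature oracle and the printed design", {
  expect_identical(power_sample_size(0.5, 0.05, 0.80), 34L)
  # independent oracle: integrate the noncentral-t power over the chi-square
  # mixing distribution instead of using pt(ncp)
  power_quad <- function(d, n, alpha) {
    df <- n - 1
    tc <- qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n)
    f <- function(u) dchisq(u, df) *
      (pnorm(-tc * sqrt(u / df) - ncp) + 1 - pnorm(tc * sqrt(u / df) - ncp))
    integrate(f, 0, df + 12 * sqrt(2 * df), rel.tol = 1e-10)$value
  }
  min_n_quad <- function(d, alpha = 0.05, power = 0.8) {
    n <- 2L
    while (power_quad(d, n, alpha) < power) n <- n + 1L
    n
  }
  for (d in c(0.2, 0.5, 0.8, 1.0))
    expect_identical(power_sample_size(d), min_n_quad(d))
  # and the closed-form R routine agrees after ceiling
  pw <- stats::power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                            power = 0.8, type = "one.sample")
  expect_identical(power_sample_size(0.5), as.integer(ceiling(pw$n)))
  expect_gt(power_sample_size(0.25), power_sample_size(0.5))
  expect_error(power_sample_size(0), "nonzero")
})

test_that("qq_points lie on the identity line for exact normal quantiles", {
  n <- 50
  x <- qnorm((seq_len(n) - 0.5) / n)
  q <- qq_points(x)
  expect_lt(max(abs(q$theoretical - q$sample)), 1e-12)
  expect_error(qq_points(1), "at least 2")
})
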