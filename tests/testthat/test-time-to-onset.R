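mk_reports <- function(event, start, sex = NULL) {
  tibble::tibble(
    primaryid = as.character(seq_along(event)),
    sex = sex %||% rep("F", length(event)),
    event_date = as.Date(event), therapy_start = as.Date(start)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("onset intervals apply the exclusion and zero-retention policy", {
  reports <- mk_reports(
    event = c("2020-03-10", "2020-03-01", NA, "2020-01-01"),
    start = c("2020-03-01", "2020-03-01", "2020-01-01", "2020-02-01")
  )
  tto <- compute_tto(reports)
  expect_equal(tto$days, c(9, 0)) # day 0 retained
  expect_equal(attr(tto, "n_excluded_missing"), 1)
  expect_equal(attr(tto, "n_excluded_negative"), 1)
})

test_that("monthly histogram uses 30-day half-open bins and conserves percent", {
  bins <- monthly_histogram(c(5, 40, 70))
  expect_equal(bins$month, c(1, 2, 3))
  expect_equal(bins$count, c(1, 1, 1))
  expect_equal(monthly_histogram(c(29, 30))$month, c(1, 2)) # boundary day 30
  big <- monthly_histogram(stats::rweibull(500, 0.7, 45))
  expect_lt(abs(sum(big$percent) - 100), 0.05 + 1e-9)
  expect_error(monthly_histogram(numeric(0)), "empty")
})

test_that("Weibull MLE agrees with an independent fitter and the exponential closed form", {
  skip_if_not_installed("fitdistrplus")
  set.seed(1)
  x <- stats::rweibull(300, shape = 0.8, scale = 40)
  fit <- fit_weibull(x)
  oracle <- fitdistrplus::fitdist(x, "weibull")
  # the oracle's general-purpose optimizer converges less tightly than the
  # profile Newton solver, so compare at its precision
  expect_equal(fit$shape, unname(oracle$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(oracle$estimate["scale"]), tolerance = 1e-3)
  # fixed shape 1: MLE scale is the sample mean
  e <- fit_weibull(x, fix_shape = 1)
  expect_equal(e$scale, mean(x))
  expect_equal(e$shape, 1)
})

test_that("Weibull fit recovers unit shape within its interval and errors on bad input", {
  set.seed(3)
  x <- stats::rweibull(500, shape = 1, scale = 30)
  fit <- fit_weibull(x)
  expect_gt(1, fit$shape_ci[1]); expect_lt(1, fit$shape_ci[2])
  expect_true(fit$shape_ci[1] < fit$shape & fit$shape < fit$shape_ci[2])
  expect_equal(fit$median, fit$scale * log(2)^(1 / fit$shape))
  expect_error(fit_weibull(c(1, 2, 3)), "at least 10")
  expect_error(fit_weibull(rep(5, 20)), "unidentifiable")
  expect_error(fit_weibull(c(-1, rep(1, 10))), "non-negative")
})

test_that("shape recovery holds across seeds and generating shapes", {
  for (beta in c(0.5, 0.68, 1, 1.5)) {
    fits <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      fit_weibull(stats::rweibull(2000, beta, 45))$shape
    }, numeric(1))
    expect_lt(abs(mean(fits) / beta - 1), 0.02, label = paste("beta", beta))
  }
})

test_that("the 95% shape interval covers the generating value in most replicates", {
  covered <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    ci <- fit_weibull(stats::rweibull(2000, 0.68, 45))$shape_ci
    ci[1] <= 0.68 && 0.68 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 18)
})

test_that("failure-type classification follows the shape rule", {
  expect_equal(classify_failure_type(0.68), "early")
  expect_equal(classify_failure_type(1.00), "random")
  expect_equal(classify_failure_type(1.04), "random")
  expect_equal(classify_failure_type(1.50), "wear-out")
})

test_that("median CI is the kernel-density normal approximation, narrowing with n", {
  x <- 1:9
  out <- median_ci_normal(x)
  expect_equal(out$median, 5)
  expect_true(out$low < 5 && out$high > 5)
  doubled <- median_ci_normal(rep(x, 2))
  expect_lt(doubled$high - doubled$low, out$high - out$low)
  # right-skewed small sample near zero can produce a negative lower bound
  set.seed(8)
  skew <- stats::rweibull(30, 0.5, 10)
  res <- median_ci_normal(skew)
  if (res$low < 0) expect_match(res$note, "negative")
  expect_error(median_ci_normal(c(1)), "at least 2")
})

test_that("cumulative incidence is a monotone curve ending at 100 with interpolated quantiles", {
  curve <- cumulative_incidence(c(10, 20, 30, 40))
  expect_equal(attr(curve, "median"), 25) # linear interpolation
  expect_equal(max(curve$cum_percent), 100)
  expect_true(all(diff(curve$cum_percent) >= 0))
  expect_true(all(diff(curve$day) > 0))
})

test_that("stratified comparison: symmetry, identity, and separation", {
  set.seed(5)
  x <- stats::rweibull(200, 0.8, 30)
  same <- compare_strata(x, x)
  expect_gt(same$wilcoxon_p[1], 0.9)
  f <- stats::rweibull(500, 0.8, 20)
  m <- stats::rweibull(500, 0.8, 60)
  sep <- compare_strata(f, m, labels = c("female", "male"))
  expect_lt(sep$wilcoxon_p[1], 0.001)
  swapped <- compare_strata(m, f)
  expect_equal(swapped$wilcoxon_p[1], sep$wilcoxon_p[1])
  expect_error(compare_strata(c(1), x), "at least 2")
  # sex-column interface
  tto <- tibble::tibble(primaryid = "1", sex = c(rep("F", 500), rep("M", 500)),
                        days = c(f, m))
  bysex <- compare_tto_by_sex(tto)
  expect_equal(bysex$stratum, c("female", "male"))
  expect_equal(bysex$wilcoxon_p[1], sep$wilcoxon_p[1])
})

test_that("histogram and cumulative curve agree at the quarter boundary", {
  set.seed(11)
  x <- round(stats::rweibull(800, 0.68, 45))
  bins <- monthly_histogram(x)
  first3 <- sum(bins$percent[bins$month <= 3])
  cum_at_90 <- 100 * mean(x < 90)
  expect_lt(abs(first3 - cum_at_90), 0.05 * 3 + 1e-9)
})
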