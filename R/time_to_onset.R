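#' Onset intervals from linked reports
#'
#' Time to onset is the difference in whole days between the adverse-event
#' date (DEMO) and the therapy start date (THER). Reports missing either date
#' are excluded and counted; negative intervals (event before therapy start,
#' usually a date error) are excluded and counted; zero is a valid onset day
#' and is retained.
#'
#' @param reports Report tibble from [link_reports()] carrying `event_date`
#'   and `therapy_start`.
#' @return A `pv_tto` tibble with columns `primaryid`, `sex`, `days`, and
#'   attributes `n_excluded_missing`, `n_excluded_negative`.
#' @export
compute_tto <- function(reports) {
  days <- as.numeric(reports$event_date - reports$therapy_start)
  missing <- is.na(days)
  negative <- !missing & days < 0
  out <- tibble::tibble(
    primaryid = reports$primaryid[!missing & !negative],
    sex = reports$sex[!missing & !negative],
    days = days[!missing & !negative]
  )
  attr(out, "n_excluded_missing") <- sum(missing)
  attr(out, "n_excluded_negative") <- sum(negative)
  class(out) <- c("pv_tto", class(out))
  out
}

tto_values <- function(x) {
  if (is.numeric(x)) x else x$days
}

#' Monthly onset histogram
#'
#' Months are 30-day half-open bins: month `m` covers days
#' `[30(m-1), 30m)`, so day 30 falls in month 2. Percentages use the sample
#' size as denominator, printed-convention rounding (2 decimals, half-up).
#'
#' @param sample A `pv_tto` tibble or numeric vector of onset days.
#' @return Tibble with columns `month`, `count`, `percent`.
#' @export
monthly_histogram <- function(sample) {
  x <- tto_values(sample)
  if (length(x) == 0) stop("empty onset sample", call. = FALSE)
  month <- floor(x / 30) + 1
  tibble::tibble(month = month) |>
    dplyr::count(.data$month, name = "count") |>
    dplyr::mutate(percent = percentage(.data$count, length(x)))
}

weibull_loglik <- function(par, x) {
  k <- par[1]; lam <- par[2]
  if (k <= 0 || lam <= 0) return(-Inf)
  n <- length(x)
  n * log(k) - n * k * log(lam) + (k - 1) * sum(log(x)) - sum((x / lam)^k)
}

#' Maximum-likelihood Weibull fit for onset times
#'
#' Fits shape and scale by profile likelihood: for a given shape the MLE
#' scale has the closed form `(mean(x^k))^{1/k}`, and the profile score in
#' the shape is solved by Newton iteration. Zero onset days are shifted to
#' 0.5 day for the likelihood only (the log-density is undefined at zero);
#' raw zeros are retained everywhere else in the package. 95% confidence
#' intervals are `estimate +/- 1.96 SE` on the natural scale, with standard
#' errors from the inverse observed information at the optimum. The median
#' and its normal-approximation CI (see [median_ci_normal()]) are attached.
#'
#' @param sample A `pv_tto` tibble or numeric vector of onset days (>= 0);
#'   at least 10 positive values after the zero shift.
#' @param fix_shape Optionally fix the shape and estimate only the scale
#'   (`fix_shape = 1` gives the exponential fit with MLE scale = mean).
#' @param max_iter,tol Newton iteration controls.
#' @return A `pv_weibull_fit` list: `shape`, `scale`, `shape_ci`, `scale_ci`,
#'   `failure_class`, `median`, `median_ci`, `log_likelihood`, `n`,
#'   `n_iter`.
#' @export
fit_weibull <- function(sample, fix_shape = NULL, max_iter = 200, tol = 1e-10) {
  raw <- tto_values(sample)
  if (any(is.na(raw))) raw <- raw[!is.na(raw)]
  if (any(raw < 0)) stop("onset times must be non-negative", call. = FALSE)
  x <- ifelse(raw == 0, 0.5, raw)
  if (length(x) < 10) stop("need at least 10 onset values", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("all onset values identical: Weibull shape is unidentifiable",
         call. = FALSE)
  }
  lx <- log(x)
  if (!is.null(fix_shape)) {
    stopifnot(fix_shape > 0)
    k <- fix_shape
    lam <- mean(x^k)^(1 / k)
    ll <- weibull_loglik(c(k, lam), x)
    se_lam <- lam / (k * sqrt(length(x)))
    fit <- list(shape = k, scale = lam, shape_ci = c(k, k),
                scale_ci = lam + c(-1.96, 1.96) * se_lam,
                log_likelihood = ll, n = length(x), n_iter = 0L)
  } else {
    # Newton on the profile score g(k) = 1/k + mean(log x) - S1/S0
    k <- 1.2825498 / stats::sd(lx) # moment-based start (pi/sqrt(6) scaling)
    if (!is.finite(k) || k <= 0) k <- 1
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- exp(k * lx)
      s0 <- sum(w); s1 <- sum(w * lx); s2 <- sum(w * lx^2)
      g <- 1 / k + mean(lx) - s1 / s0
      gp <- -1 / k^2 - (s2 * s0 - s1^2) / s0^2
      step <- g / gp
      k_new <- k - step
      if (k_new <= 0) k_new <- k / 2 # damped step keeps the shape positive
      trace <- c(trace, k_new)
      if (abs(k_new - k) < tol * max(1, k)) {
        k <- k_new; converged <- TRUE; break
      }
      k <- k_new
    }
    if (!converged) {
      stop("Weibull shape iteration did not converge after ", max_iter,
           " steps; trace tail: ",
           paste(signif(utils::tail(trace, 5), 6), collapse = ", "),
           call. = FALSE)
    }
    lam <- mean(x^k)^(1 / k)
    ll <- weibull_loglik(c(k, lam), x)
    hess <- stats::optimHess(c(k, lam), weibull_loglik, x = x)
    vcov <- solve(-hess)
    se <- sqrt(diag(vcov))
    fit <- list(shape = k, scale = lam,
                shape_ci = k + c(-1.96, 1.96) * se[1],
                scale_ci = lam + c(-1.96, 1.96) * se[2],
                log_likelihood = ll, n = length(x), n_iter = it)
  }
  fit$failure_class <- classify_failure_type(fit$shape)
  fit$median <- fit$scale * log(2)^(1 / fit$shape)
  mci <- median_ci_normal(raw)
  fit$median_ci <- c(mci$low, mci$high)
  fit$sample_median <- mci$median
  class(fit) <- "pv_weibull_fit"
  fit
}

#' Classify the hazard trend implied by the Weibull shape
#'
#' Shape below 1 means a decreasing hazard ("early failure": events cluster
#' shortly after treatment initiation), 1 a constant hazard ("random"), above
#' 1 an increasing hazard ("wear-out"). A tolerance band of +/- 0.05 around 1
#' is treated as random.
#'
#' @param fit A `pv_weibull_fit` or a numeric shape value.
#' @return `"early"`, `"random"`, or `"wear-out"`.
#' @export
classify_failure_type <- function(fit) {
  beta <- if (inherits(fit, "pv_weibull_fit")) fit$shape else fit
  if (abs(beta - 1) <= 0.05) "random"
  else if (beta < 1) "early"
  else "wear-out"
}

#' @export
print.pv_weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull onset fit (n = %d)\n", x$n))
  cat(sprintf("  shape %.3f (95%% CI %.3f-%.3f) -> %s failure type\n",
              x$shape, x$shape_ci[1], x$shape_ci[2], x$failure_class))
  cat(sprintf("  scale %.1f days (95%% CI %.1f-%.1f)\n",
              x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  parametric median %.1f days; sample median %.1f (95%% CI %.1f to %.1f)\n",
              x$median, x$sample_median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Normal-approximation confidence interval for the median onset
#'
#' `median +/- 1.96 SE` with `SE = 1 / (2 f(median) sqrt(n))`, the density at
#' the median estimated by a Gaussian kernel. The lower bound is reported
#' unclipped and can be negative — an artefact of the normal approximation,
#' since true onset times are non-negative; the `note` column records this.
#'
#' @param sample A `pv_tto` tibble or numeric vector (n >= 2).
#' @return One-row tibble: `median`, `low`, `high`, `note`.
#' @export
median_ci_normal <- function(sample) {
  x <- tto_values(sample)
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- stats::median(x)
  dens <- stats::density(x)
  fhat <- stats::approx(dens$x, dens$y, xout = m, rule = 2)$y
  se <- 1 / (2 * fhat * sqrt(length(x)))
  low <- m - 1.96 * se
  high <- m + 1.96 * se
  tibble::tibble(
    median = m, low = low, high = high,
    note = ifelse(low < 0,
                  "lower bound negative under the normal approximation; true onset times are non-negative",
                  NA_character_)
  )
}

#' Empirical cumulative incidence of onset
#'
#' The empirical CDF as a step function in percent, with linear-interpolation
#' quantiles for the median and interquartile range attached as attributes
#' `median`, `q1`, `q3`.
#'
#' @param sample A `pv_tto` tibble or numeric vector.
#' @return Tibble with columns `day`, `cum_percent` (one row per distinct
#'   onset day, last point at 100).
#' @export
cumulative_incidence <- function(sample) {
  x <- sort(tto_values(sample))
  if (length(x) == 0) stop("empty onset sample", call. = FALSE)
  n <- length(x)
  curve <- tibble::tibble(day = x, cum_percent = 100 * seq_len(n) / n) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(cum_percent = max(.data$cum_percent), .groups = "drop")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  attr(curve, "q1") <- qs[1]
  attr(curve, "median") <- qs[2]
  attr(curve, "q3") <- qs[3]
  curve
}

#' Compare onset between two strata
#'
#' Medians and interquartile ranges per stratum (linear-interpolation
#' quantiles on the raw days, zeros retained) and a two-sided Wilcoxon
#' rank-sum test with tie correction under the normal approximation.
#'
#' @param sample_a,sample_b `pv_tto` tibbles or numeric vectors (each n >= 2).
#' @param labels Length-2 stratum labels for the output.
#' @return Tibble with one row per stratum (`stratum`, `n`, `median`, `q1`,
#'   `q3`) and the shared `wilcoxon_p` column.
#' @export
compare_strata <- function(sample_a, sample_b, labels = c("a", "b")) {
  xa <- tto_values(sample_a); xb <- tto_values(sample_b)
  if (length(xa) < 2 || length(xb) < 2) {
    stop("each stratum needs at least 2 onset values", call. = FALSE)
  }
  p <- stats::wilcox.test(xa, xb, exact = FALSE, correct = FALSE)$p.value
  summarise_one <- function(x, lab) {
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(stratum = lab, n = length(x), median = qs[2],
                   q1 = qs[1], q3 = qs[3])
  }
  dplyr::bind_rows(summarise_one(xa, labels[1]), summarise_one(xb, labels[2])) |>
    dplyr::mutate(wilcoxon_p = p)
}

#' Sex-stratified onset comparison
#'
#' Splits a `pv_tto` sample on its `sex` column (reports with unknown sex are
#' dropped) and runs [compare_strata()] female versus male.
#'
#' @param sample A `pv_tto` tibble with a `sex` column.
#' @return See [compare_strata()].
#' @export
compare_tto_by_sex <- function(sample) {
  stopifnot("sex" %in% names(sample))
  f <- sample$days[!is.na(sample$sex) & sample$sex == "F"]
  m <- sample$days[!is.na(sample$sex) & sample$sex == "M"]
  compare_strata(f, m, labels = c("female", "male"))
}
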