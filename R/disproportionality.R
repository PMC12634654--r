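#' Build drug-event 2x2 contingency tables
#'
#' For every event observed in either group, counts distinct reports:
#' `a` = cohort reports mentioning the event, `b` = remaining cohort reports,
#' `c` = background reports mentioning the event, `d` = remaining background,
#' plus the database size `N = a+b+c+d` (identical across events) and the
#' expected count under independence `E = (a+b)(a+c)/N`.
#'
#' At the SOC level each report contributes at most once per system organ
#' class, regardless of how many of its PTs map there (report-level 2x2
#' semantics); set `soc_event_level = TRUE` to instead count every mapped PT
#' mention.
#'
#' @param cohort,background Report tibbles from [primary_suspect_cohort()].
#' @param level `"PT"` (default) or `"SOC"`.
#' @param dictionary A `pv_meddra`; required when `level = "SOC"`.
#' @param soc_event_level Count PT mentions instead of distinct reports per
#'   SOC.
#' @return Tibble with columns `event`, `level`, `a`, `b`, `c`, `d`, `N`, `E`.
#' @export
build_contingency <- function(cohort, background, level = c("PT", "SOC"),
                              dictionary = NULL, soc_event_level = FALSE) {
  level <- match.arg(level)
  if (nrow(background) == 0) {
    stop("background is empty: a comparator population is required",
         call. = FALSE)
  }
  if (level == "SOC" && is.null(dictionary)) {
    stop("SOC-level tables require a dictionary (see load_meddra())",
         call. = FALSE)
  }
  pairs <- function(reports) {
    x <- tibble::tibble(
      primaryid = rep(reports$primaryid, lengths(reports$reactions)),
      event = unlist(reports$reactions, use.names = FALSE)
    )
    x <- dplyr::distinct(x)
    if (level == "SOC") {
      x$event <- as.character(pt_to_soc(dictionary, x$event))
      if (!soc_event_level) x <- dplyr::distinct(x)
    }
    x
  }
  co <- pairs(cohort)
  bg <- pairs(background)
  events <- sort(unique(c(co$event, bg$event)))
  a <- table(factor(co$event, levels = events))
  cc <- table(factor(bg$event, levels = events))
  n_co <- nrow(cohort)
  n_bg <- nrow(background)
  out <- tibble::tibble(
    event = events, level = level,
    a = as.integer(a), b = n_co - as.integer(a),
    c = as.integer(cc), d = n_bg - as.integer(cc)
  )
  out$N <- out$a + out$b + out$c + out$d
  out$E <- (as.numeric(out$a) + out$b) * (as.numeric(out$a) + out$c) / out$N
  out
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; the interval is `exp(log ROR +/- 1.96 sqrt(1/a + 1/b
#' + 1/c + 1/d))`. With any zero cell the estimator is undefined and returns
#' `NA` unless `continuity = TRUE`, which adds the Haldane 0.5 to all four
#' cells (for the ROR only).
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (see
#'   [build_contingency()]).
#' @param continuity Apply the 0.5 continuity correction to zero-cell tables.
#' @return Input tibble with columns `ror`, `ror_low`, `ror_high` appended.
#' @export
ror <- function(tables, continuity = FALSE) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  if (continuity) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    cc <- cc + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  est <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  low <- exp(log(est) - 1.96 * se)
  high <- exp(log(est) + 1.96 * se)
  est[zero] <- NA_real_; low[zero] <- NA_real_; high[zero] <- NA_real_
  dplyr::mutate(tables, ror = est, ror_low = low, ror_high = high)
}

#' Proportional reporting ratio and Yates-corrected chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square statistic uses the Yates
#' continuity correction `N(|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`,
#' floored at zero (set `yates = FALSE` for the uncorrected statistic).
#' `a = 0` gives PRR 0; `c = 0` with `a > 0` leaves PRR undefined (`NA`).
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d`.
#' @param yates Apply the Yates continuity correction.
#' @return Input tibble with columns `prr`, `chi2` appended.
#' @export
prr <- function(tables, yates = TRUE) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  N <- a + b + cc + d
  est <- (a / (a + b)) / (cc / (cc + d))
  est[a == 0] <- 0
  est[cc == 0 & a > 0] <- NA_real_
  dev <- abs(a * d - b * cc) - ifelse(yates, N / 2, 0)
  dev <- pmax(dev, 0)
  chi2 <- N * dev^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  chi2[(a + cc) == 0 | (b + d) == 0] <- 0
  dplyr::mutate(tables, prr = est, chi2 = chi2)
}

# hyperparameters of the information-component prior: Dirichlet/beta margins
# with prior IC expectation centred at zero
bcpnn_hyper <- list(alpha1 = 1, alpha = 2, beta1 = 1, beta = 2, gamma11 = 1)

#' Bayesian confidence propagation information component
#'
#' Closed-form posterior moments of
#' `IC = log2[p(drug, event) / (p(drug) p(event))]` under independent
#' beta-margin priors whose hyperparameters centre the prior IC expectation
#' at zero: the posterior mean and variance of each `log p` term are digamma
#' and trigamma functions of the updated beta parameters. The lower
#' credibility bound is `ic025 = E(IC) - 2 sd(IC)`. Defined for `a = 0`.
#'
#' `method = "shrinkage"` substitutes the simpler shrinkage estimator
#' `IC = log2[(a + 0.5)/(E + 0.5)]` with a gamma-based lower bound.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d`.
#' @param method `"closed_form"` (default) or `"shrinkage"`.
#' @return Input tibble with columns `ic`, `ic025` appended.
#' @export
bcpnn_ic <- function(tables, method = c("closed_form", "shrinkage")) {
  method <- match.arg(method)
  a <- tables$a; b <- tables$b; cc <- tables$c; d <- tables$d
  N <- a + b + cc + d
  if (method == "shrinkage") {
    E <- (a + b) * (a + cc) / N
    ic <- log2((a + 0.5) / (E + 0.5))
    ic025 <- log2(stats::qgamma(0.025, a + 0.5, rate = 1) / (E + 0.5))
    return(dplyr::mutate(tables, ic = ic, ic025 = ic025))
  }
  h <- bcpnn_hyper
  c1 <- a + b      # drug margin
  c2 <- a + cc     # event margin
  # joint-cell prior Beta(gamma11, gam - gamma11) with gam chosen so the
  # prior expectation of IC is zero
  gam <- h$gamma11 * (N + h$alpha) * (N + h$beta) /
    ((c1 + h$alpha1) * (c2 + h$beta1))
  ic <- (digamma(a + h$gamma11) - digamma(N + gam) -
           (digamma(c1 + h$alpha1) - digamma(N + h$alpha)) -
           (digamma(c2 + h$beta1) - digamma(N + h$beta))) / log(2)
  vic <- (trigamma(a + h$gamma11) - trigamma(N + gam) +
            trigamma(c1 + h$alpha1) - trigamma(N + h$alpha) +
            trigamma(c2 + h$beta1) - trigamma(N + h$beta)) / log(2)^2
  dplyr::mutate(tables, ic = ic, ic025 = ic - 2 * sqrt(vic))
}

nb_mix_loglik <- function(theta, a, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  f1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  f2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(f1, f2)
  sum(m + log(w * exp(f1 - m) + (1 - w) * exp(f2 - m)))
}

#' Fit the empirical-Bayes gamma-Poisson mixture prior
#'
#' Maximizes the summed marginal log-likelihood of the observed counts under
#' `a ~ Poisson(lambda E)` with the reporting-rate multiplier `lambda` drawn
#' from a two-component gamma mixture `w Gamma(alpha1, beta1) + (1 - w)
#' Gamma(alpha2, beta2)` (shape/rate). The marginal is a mixture of negative
#' binomials; optimization runs on log/logit-transformed parameters from the
#' conventional starting point `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param tables Tibble with columns `a` and `E`; at least 20 rows with
#'   `E > 0` are required.
#' @param init Starting values `c(alpha1, beta1, alpha2, beta2, w)`.
#' @return A `pv_gps_prior` with elements `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `mix_p`, `log_likelihood`, `converged`, `n_tables`.
#' @export
fit_gps_prior <- function(tables, init = c(0.2, 0.1, 2, 4, 1 / 3)) {
  keep <- tables$E > 0
  a <- tables$a[keep]; E <- tables$E[keep]
  if (length(a) < 20) {
    stop("need at least 20 tables with E > 0 to fit the mixture prior",
         call. = FALSE)
  }
  if (all(a == 0)) stop("degenerate data: all observed counts are zero",
                        call. = FALSE)
  theta0 <- c(log(init[1:4]), stats::qlogis(init[5]))
  # box constraints keep the components away from degenerate point masses
  # (unbounded ML can push a gamma component to an infinite-precision spike)
  fit <- stats::optim(theta0, nb_mix_loglik, a = a, E = E,
                      control = list(fnscale = -1, maxit = 2000,
                                     factr = 1e4),
                      method = "L-BFGS-B", lower = rep(-7, 5),
                      upper = rep(7, 5))
  if (fit$convergence != 0) {
    stop("mixture prior optimization did not converge (code ",
         fit$convergence, "): ", fit$message, call. = FALSE)
  }
  structure(
    list(alpha1 = exp(fit$par[1]), beta1 = exp(fit$par[2]),
         alpha2 = exp(fit$par[3]), beta2 = exp(fit$par[4]),
         mix_p = stats::plogis(fit$par[5]),
         log_likelihood = fit$value, converged = TRUE,
         n_tables = length(a)),
    class = "pv_gps_prior"
  )
}

#' Construct a gamma-mixture prior directly
#'
#' @param alpha1,beta1,alpha2,beta2 Positive gamma shape/rate parameters.
#' @param mix_p Weight of the first component, in `[0, 1]`.
#' @return A `pv_gps_prior`.
#' @export
gps_prior <- function(alpha1, beta1, alpha2 = alpha1, beta2 = beta1,
                      mix_p = 1) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0,
            mix_p >= 0, mix_p <= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, mix_p = mix_p, log_likelihood = NA_real_,
                 converged = NA, n_tables = NA_integer_),
            class = "pv_gps_prior")
}

#' @export
print.pv_gps_prior <- function(x, ...) {
  cat("<pv_gps_prior> w =", signif(x$mix_p, 4),
      "| Gamma(", signif(x$alpha1, 4), ",", signif(x$beta1, 4), ") /",
      "Gamma(", signif(x$alpha2, 4), ",", signif(x$beta2, 4), ")\n")
  invisible(x)
}

#' Empirical-Bayes geometric mean and its posterior 5th percentile
#'
#' Given the mixture prior, the posterior of the reporting-rate multiplier is
#' a mixture of `Gamma(alpha_j + a, beta_j + E)` with weights proportional to
#' prior weight times negative-binomial evidence. `EBGM = 2^{E[log2 lambda]}`
#' (the posterior geometric mean) and `EBGM05` is the posterior 5th
#' percentile, found by root-finding on the mixture CDF to a relative
#' tolerance of 1e-6.
#'
#' @param tables Tibble with columns `a` and `E` (`E > 0`).
#' @param prior A `pv_gps_prior` from [fit_gps_prior()] or [gps_prior()].
#' @return Input tibble with columns `ebgm`, `ebgm05` appended.
#' @export
ebgm <- function(tables, prior) {
  stopifnot(inherits(prior, "pv_gps_prior"))
  a <- tables$a; E <- tables$E
  if (any(E <= 0)) stop("EBGM undefined for tables with E <= 0", call. = FALSE)
  lw1 <- log(prior$mix_p) +
    stats::dnbinom(a, size = prior$alpha1,
                   prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  lw2 <- log(1 - prior$mix_p) +
    stats::dnbinom(a, size = prior$alpha2,
                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(lw1, lw2)
  q1 <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  q1[prior$mix_p == 1] <- 1
  q1[prior$mix_p == 0] <- 0
  sh1 <- prior$alpha1 + a; rt1 <- prior$beta1 + E
  sh2 <- prior$alpha2 + a; rt2 <- prior$beta2 + E
  elog <- q1 * (digamma(sh1) - log(rt1)) + (1 - q1) * (digamma(sh2) - log(rt2))
  est <- exp(elog)
  e05 <- vapply(seq_along(a), function(i) {
    mix_gamma_quantile(0.05, q1[i], sh1[i], rt1[i], sh2[i], rt2[i])
  }, numeric(1))
  dplyr::mutate(tables, ebgm = est, ebgm05 = e05)
}

mix_gamma_quantile <- function(p, w, sh1, rt1, sh2, rt2) {
  cdf <- function(q) {
    w * stats::pgamma(q, sh1, rate = rt1) +
      (1 - w) * stats::pgamma(q, sh2, rate = rt2) - p
  }
  q1p <- stats::qgamma(p, sh1, rate = rt1)
  q2p <- stats::qgamma(p, sh2, rate = rt2)
  if (abs(q1p - q2p) < 1e-12 * max(q1p, 1e-12)) return(q1p)
  # widen beyond the component quantiles so the endpoint signs are strict
  lo <- 0.5 * min(q1p, q2p)
  hi <- 2 * max(q1p, q2p)
  stats::uniroot(cdf, c(lo, hi), tol = 1e-6 * max(hi, 1e-12))$root
}

#' Thresholds of the combined signal rule
#'
#' The conventional six-condition conjunction: co-occurrence count `a >= 3`,
#' `PRR >= 2`, chi-square `>= 4`, lower 95% ROR bound `> 1`, `IC025 > 0`,
#' `EBGM05 > 2`. Every threshold is adjustable.
#'
#' @param min_count,min_prr,min_chi2,min_ror_low,min_ic025,min_ebgm05
#'   Threshold values.
#' @return Named list of thresholds.
#' @export
signal_thresholds <- function(min_count = 3, min_prr = 2, min_chi2 = 4,
                              min_ror_low = 1, min_ic025 = 0,
                              min_ebgm05 = 2) {
  list(min_count = min_count, min_prr = min_prr, min_chi2 = min_chi2,
       min_ror_low = min_ror_low, min_ic025 = min_ic025,
       min_ebgm05 = min_ebgm05)
}

#' Apply the six-condition signal rule
#'
#' A pair is flagged iff all six conditions hold simultaneously; an
#' undefined statistic (e.g. ROR with a zero cell) never yields a signal.
#'
#' @param rows Tibble carrying `a`, `prr`, `chi2`, `ror_low`, `ic025`,
#'   `ebgm05`.
#' @param thresholds From [signal_thresholds()].
#' @return Input tibble with logical column `signal` appended.
#' @export
apply_signal_rule <- function(rows, thresholds = signal_thresholds()) {
  t <- thresholds
  flag <- rows$a >= t$min_count &
    rows$prr >= t$min_prr &
    rows$chi2 >= t$min_chi2 &
    rows$ror_low > t$min_ror_low &
    rows$ic025 > t$min_ic025 &
    rows$ebgm05 > t$min_ebgm05
  dplyr::mutate(rows, signal = dplyr::coalesce(flag, FALSE))
}

#' Compute all four estimators and the signal flag for a set of tables
#'
#' Convenience wrapper chaining [ror()], [prr()], [bcpnn_ic()],
#' [fit_gps_prior()] (unless a prior is supplied), [ebgm()] and
#' [apply_signal_rule()].
#'
#' @param tables From [build_contingency()].
#' @param prior Optional `pv_gps_prior`; fitted from `tables` when `NULL`.
#' @param ic_method Passed to [bcpnn_ic()].
#' @param thresholds Passed to [apply_signal_rule()].
#' @param continuity Passed to [ror()].
#' @return A `pv_signal_table` tibble with one row per event carrying the
#'   2x2 cells, all estimators with interval bounds, and the `signal` flag.
#'   The fitted prior is attached as the `gps_prior` attribute.
#' @export
signal_stats <- function(tables, prior = NULL,
                         ic_method = c("closed_form", "shrinkage"),
                         thresholds = signal_thresholds(),
                         continuity = FALSE) {
  ic_method <- match.arg(ic_method)
  if (is.null(prior)) prior <- fit_gps_prior(tables)
  out <- tables |>
    ror(continuity = continuity) |>
    prr() |>
    bcpnn_ic(method = ic_method) |>
    ebgm(prior = prior) |>
    apply_signal_rule(thresholds = thresholds)
  attr(out, "gps_prior") <- prior
  class(out) <- c("pv_signal_table", class(out))
  out
}

#' Rank signal rows
#'
#' Stable descending sort by ROR or co-occurrence count, ties broken by event
#' name ascending; `NA` estimates sort last.
#'
#' @param rows A signal tibble.
#' @param by `"ror"` or `"count"`.
#' @param k Number of rows to keep (all if larger than the row count).
#' @return Reordered tibble of at most `k` rows.
#' @export
rank_signals <- function(rows, by = c("ror", "count"), k = Inf) {
  by <- match.arg(by)
  key <- if (by == "ror") rows$ror else rows$a
  ord <- order(-key, rows$event, na.last = TRUE)
  utils::head(rows[ord, ], min(k, nrow(rows)))
}
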