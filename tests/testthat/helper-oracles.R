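# Independent oracles used to freeze expected values. These deliberately do
# not share code with the implementation paths they check.

# Posterior mean/quantile of the gamma-Poisson reporting-rate multiplier by
# direct numerical integration over an unnormalized posterior density grid:
# prior(lambda) * lambda^a * exp(-lambda E).
ebgm_quadrature_oracle <- function(a, E, alpha1, beta1, alpha2, beta2, w) {
  log_prior <- function(l) {
    # log-space mixture to survive far-tail evaluation
    l1 <- log(w) + stats::dgamma(l, alpha1, rate = beta1, log = TRUE)
    l2 <- log(1 - w) + stats::dgamma(l, alpha2, rate = beta2, log = TRUE)
    m <- pmax(l1, l2)
    m + log(exp(l1 - m) + exp(l2 - m))
  }
  log_post <- function(l) log_prior(l) + a * log(l) - l * E
  # log-spaced grid spanning both posterior components' extreme quantiles
  lo <- min(stats::qgamma(1e-10, alpha1 + a, rate = beta1 + E),
            stats::qgamma(1e-10, alpha2 + a, rate = beta2 + E))
  hi <- max(stats::qgamma(1 - 1e-12, alpha1 + a, rate = beta1 + E),
            stats::qgamma(1 - 1e-12, alpha2 + a, rate = beta2 + E))
  lgrid <- seq(log(max(lo, 1e-300)), log(hi), length.out = 400000)
  grid <- exp(lgrid)
  lp <- log_post(grid) + lgrid # Jacobian of the log transform
  wgt <- exp(lp - max(lp))
  z <- sum(wgt)
  geo <- exp(sum(wgt * lgrid) / z)
  cdf <- cumsum(wgt) / z
  q05 <- stats::approx(cdf, grid, xout = 0.05, ties = "ordered")$y
  list(ebgm = geo, ebgm05 = q05)
}

# Monte-Carlo posterior of the information component under the beta-margin
# model: independent beta posteriors for p(drug), p(event), p(drug & event)
# with the same hyperparameters the closed form uses.
bcpnn_mc_oracle <- function(a, b, cc, d, n_draws = 1e5, seed = 99) {
  set.seed(seed)
  N <- a + b + cc + d
  c1 <- a + b; c2 <- a + cc
  al1 <- 1; al <- 2; be1 <- 1; be <- 2; g11 <- 1
  gam <- g11 * (N + al) * (N + be) / ((c1 + al1) * (c2 + be1))
  p1 <- stats::rbeta(n_draws, c1 + al1, N - c1 + al - al1)
  p2 <- stats::rbeta(n_draws, c2 + be1, N - c2 + be - be1)
  p11 <- stats::rbeta(n_draws, a + g11, N - a + gam - g11)
  mean(log2(p11 / (p1 * p2)))
}

# small hand-checkable report set: 3 cohort reports (2 with event X),
# 3 background reports (1 with X)
toy_split <- function() {
  mk <- function(pid, pts, target) {
    tibble::tibble(
      primaryid = pid, caseid = pid,
      fda_date = as.Date("2020-01-01"), event_date = as.Date("2020-02-01"),
      event_year = 2020L, report_year = 2020L, sex = "F", age_years = 50,
      country = "US", reporter = "MD",
      drug_names = list(if (target) "TARGET" else "OTHER"),
      drug_roles = list("PS"),
      reactions = list(pts), outcomes = list(character(0)),
      therapy_start = as.Date("2020-01-15"), serious = FALSE
    )
  }
  cohort <- dplyr::bind_rows(
    mk("1", c("X", "Y"), TRUE), mk("2", "X", TRUE), mk("3", "Y", TRUE)
  )
  background <- dplyr::bind_rows(
    mk("4", "X", FALSE), mk("5", "Y", FALSE), mk("6", "Z", FALSE)
  )
  list(cohort = cohort, background = background)
}

bin_ages_for_test <- function(ages, bins) pvsignal:::bin_ages(ages, bins)

small_config <- function(...) {
  synthetic_config(n_reports = 400, seed = 7, ...)
}

# shared pipeline fragment: bundle -> dedup -> link -> cohort split
run_core <- function(config, drug = "FENOFIBRIC ACID") {
  b <- generate_bundle(config)
  demo <- deduplicate_demo(b$demo)
  reports <- suppressMessages(
    link_reports(demo, b$drug, b$reac, b$ther, b$outc, drug_names = drug)
  )
  sp <- primary_suspect_cohort(reports, drug)
  list(bundle = b, demo = demo, reports = reports,
       cohort = sp$cohort, background = sp$background)
}
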