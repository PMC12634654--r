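test_that("2x2 construction matches hand enumeration on the toy set", {
  split <- toy_split()
  tab <- build_contingency(split$cohort, split$background, "PT")
  x <- tab[tab$event == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(2, 1, 1, 2))
  expect_equal(x$N, 6)
  expect_equal(x$E, 3 * 3 / 6)
  z <- tab[tab$event == "Z", ]
  expect_equal(c(z$a, z$b, z$c, z$d), c(0, 3, 1, 2))
  # conservation: sum of a equals distinct cohort (report, PT) mentions
  mentions <- nrow(dplyr::distinct(tibble::tibble(
    id = rep(split$cohort$primaryid, lengths(split$cohort$reactions)),
    pt = unlist(split$cohort$reactions)
  )))
  expect_equal(sum(tab$a), mentions)
  expect_error(build_contingency(split$cohort, split$background[0, ]),
               "comparator")
  expect_error(build_contingency(split$cohort, split$background, "SOC"),
               "dictionary")
})

test_that("ROR formula, interval, and zero-cell policy", {
  tab <- tibble::tibble(a = 5, b = 95, c = 100, d = 9800)
  out <- ror(tab)
  expect_equal(round(out$ror, 3), 5.158)
  expect_gt(out$ror_low, 1) # CI excludes the null
  expect_lt(out$ror_low, out$ror)
  expect_gt(out$ror_high, out$ror)
  # independence: a*d == b*c
  ind <- ror(tibble::tibble(a = 10, b = 90, c = 100, d = 900))
  expect_equal(ind$ror, 1)
  # zero cell undefined unless continuity correction requested
  zc <- tibble::tibble(a = 0, b = 100, c = 50, d = 9850)
  expect_true(is.na(ror(zc)$ror))
  cc <- ror(zc, continuity = TRUE)
  expect_false(is.na(cc$ror))
  expect_equal(cc$ror, (0.5 * 9850.5) / (100.5 * 50.5))
})

test_that("PRR and Yates chi-square match direct evaluation", {
  tab <- tibble::tibble(a = 5, b = 95, c = 100, d = 9800)
  out <- prr(tab)
  expect_equal(round(out$prr, 3), 4.950)
  # oracle: base chisq.test with continuity correction
  m <- matrix(c(5, 95, 100, 9800), 2, byrow = TRUE)
  expect_equal(out$chi2, unname(suppressWarnings(stats::chisq.test(m)$statistic)))
  ind <- prr(tibble::tibble(a = 10, b = 90, c = 100, d = 900))
  expect_equal(ind$prr, 1)
  expect_lt(ind$chi2, 0.5)
  expect_equal(prr(tibble::tibble(a = 0, b = 10, c = 5, d = 100))$prr, 0)
  expect_true(is.na(prr(tibble::tibble(a = 3, b = 10, c = 0, d = 100))$prr))
})

test_that("information component is near 0 at independence, negative for deficits, and matches Monte Carlo", {
  ind <- bcpnn_ic(tibble::tibble(a = 100, b = 900, c = 900, d = 8100))
  expect_lt(abs(ind$ic), 0.05)
  deficit <- bcpnn_ic(tibble::tibble(a = 0, b = 1000, c = 1000, d = 8000))
  expect_lt(deficit$ic, 0)
  out <- bcpnn_ic(tibble::tibble(a = 5, b = 95, c = 100, d = 9800))
  mc <- bcpnn_mc_oracle(5, 95, 100, 9800)
  expect_lt(abs(out$ic - mc), 0.02)
  expect_lt(out$ic025, out$ic)
  # shrinkage variant: log2((a + .5)/(E + .5))
  sh <- bcpnn_ic(tibble::tibble(a = 5, b = 95, c = 100, d = 9800),
                 method = "shrinkage")
  E <- 100 * 105 / 10000
  expect_equal(sh$ic, log2(5.5 / (E + 0.5)))
})

test_that("gamma-mixture prior fit recovers a single-gamma truth and is order-invariant", {
  set.seed(42)
  E <- stats::runif(100, 5, 50)
  lam <- stats::rgamma(100, 2, rate = 4)
  a <- stats::rpois(100, lam * E)
  tab <- tibble::tibble(a = a, E = E)
  fit <- fit_gps_prior(tab)
  expect_true(fit$converged)
  expect_true(all(c(fit$alpha1, fit$beta1, fit$alpha2, fit$beta2) > 0))
  expect_true(fit$mix_p >= 0 && fit$mix_p <= 1)
  # fitted marginal likelihood at least matches the generating prior's
  gen_ll <- sum(stats::dnbinom(a, size = 2, prob = 4 / (4 + E), log = TRUE))
  expect_gte(fit$log_likelihood, gen_ll - 1)
  refit <- fit_gps_prior(tab[sample(nrow(tab)), ])
  expect_equal(refit$log_likelihood, fit$log_likelihood)
  expect_equal(refit$alpha1, fit$alpha1)
  expect_error(fit_gps_prior(tab[1:5, ]), "at least 20")
  expect_error(fit_gps_prior(tibble::tibble(a = rep(0L, 30), E = rep(1, 30))),
               "degenerate")
})

test_that("EBGM has the conjugate closed form for a single-component prior", {
  prior <- gps_prior(alpha1 = 2, beta1 = 4, mix_p = 1)
  tab <- tibble::tibble(a = c(0, 3, 20), E = c(2, 5, 10))
  out <- ebgm(tab, prior)
  sh <- 2 + tab$a; rt <- 4 + tab$E
  expect_equal(out$ebgm, exp(digamma(sh) - log(rt)))
  expect_equal(out$ebgm05, stats::qgamma(0.05, sh, rate = rt), tolerance = 1e-5)
  expect_error(ebgm(tibble::tibble(a = 1, E = 0), prior), "E <= 0")
})

test_that("EBGM shrinks small counts toward the prior and matches quadrature", {
  prior <- gps_prior(alpha1 = 0.5, beta1 = 0.5, alpha2 = 4, beta2 = 4,
                     mix_p = 0.4)
  # small a with a/E = 10: estimate shrinks below the raw ratio
  small <- ebgm(tibble::tibble(a = 5, E = 0.5), prior)
  expect_lt(small$ebgm, 10)
  oracle <- ebgm_quadrature_oracle(5, 0.5, 0.5, 0.5, 4, 4, 0.4)
  expect_lt(abs(small$ebgm / oracle$ebgm - 1), 0.01)
  expect_lt(abs(small$ebgm05 / oracle$ebgm05 - 1), 0.01)
  # large a with a/E = 1: data dominate
  big <- ebgm(tibble::tibble(a = 1000, E = 1000), prior)
  expect_lt(abs(big$ebgm - 1), 0.05)
})

test_that("signal rule is the strict six-condition conjunction", {
  base <- tibble::tibble(a = 10, prr = 3, chi2 = 12, ror_low = 1.4,
                         ic025 = 0.3, ebgm05 = 2.5)
  expect_true(apply_signal_rule(base)$signal)
  for (tweak in list(c("prr", 1.9), c("a", 2), c("chi2", 3.9),
                     c("ror_low", 1), c("ic025", 0), c("ebgm05", 2))) {
    row <- base
    row[[tweak[1]]] <- as.numeric(tweak[2])
    expect_false(apply_signal_rule(row)$signal, label = tweak[1])
  }
  na_row <- base; na_row$ror_low <- NA_real_
  expect_false(apply_signal_rule(na_row)$signal)
})

test_that("all four estimators are nondecreasing in a with other cells fixed", {
  prior <- gps_prior(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 4, mix_p = 0.5)
  a <- 1:40
  tab <- tibble::tibble(a = a, b = 200, c = 100, d = 5000)
  tab$N <- tab$a + tab$b + tab$c + tab$d
  tab$E <- (tab$a + tab$b) * (tab$a + tab$c) / tab$N
  out <- tab |> ror() |> prr() |> bcpnn_ic() |> ebgm(prior = prior)
  expect_true(all(diff(out$ror) > 0))
  expect_true(all(diff(out$prr) > 0))
  expect_true(all(diff(out$ic) > 0))
  expect_true(all(diff(out$ebgm) > 0))
})

test_that("ranking sorts descending with alphabetical tie-break", {
  rows <- tibble::tibble(
    event = c("B", "A", "C", "D"),
    a = c(5L, 5L, 9L, 1L),
    ror = c(2, 2, 1.5, NA)
  )
  by_ror <- rank_signals(rows, "ror")
  expect_equal(by_ror$event, c("A", "B", "C", "D")) # tie at 2 -> A before B
  by_count <- rank_signals(rows, "count", k = 2)
  expect_equal(by_count$event, c("C", "A"))
  expect_equal(nrow(rank_signals(rows, "ror", k = 100)), 4)
})
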