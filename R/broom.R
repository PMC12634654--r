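#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Weibull onset fit
#'
#' @param x A `pv_weibull_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.pv_weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    conf.low = c(x$shape_ci[1], x$scale_ci[1]),
    conf.high = c(x$shape_ci[2], x$scale_ci[2])
  )
}

#' Glance at a Weibull onset fit
#'
#' @param x A `pv_weibull_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `log_likelihood`, `failure_class`, `median`,
#'   `median_conf.low`, `median_conf.high`.
#' @export
glance.pv_weibull_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, log_likelihood = x$log_likelihood,
    failure_class = x$failure_class, median = x$median,
    median_conf.low = x$median_ci[1], median_conf.high = x$median_ci[2]
  )
}

#' Tidy a gamma-mixture prior
#'
#' @param x A `pv_gps_prior`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.pv_gps_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "mix_p"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$mix_p)
  )
}

#' Glance at a gamma-mixture prior fit
#'
#' @param x A `pv_gps_prior`.
#' @param ... Unused.
#' @return One-row tibble: `log_likelihood`, `converged`, `n_tables`.
#' @export
glance.pv_gps_prior <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, converged = x$converged,
                 n_tables = x$n_tables)
}
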