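#' Percentage of a cohort, at printed precision
#'
#' Published baseline tables print stratum percentages to two decimals with
#' halves rounded up; this reproduces that convention so printed (count,
#' percent) pairs recompute exactly.
#'
#' @param n Stratum count (0 <= n <= total).
#' @param total Cohort size (> 0).
#' @return Percentage rounded half-up to 2 decimals.
#' @examples
#' percentage(155, 323) # 47.99
#' @export
percentage <- function(n, total) {
  if (any(total <= 0)) stop("percentage undefined for total <= 0", call. = FALSE)
  if (any(n < 0 | n > total)) stop("need 0 <= n <= total", call. = FALSE)
  round_half_up(100 * n / total, 2)
}

#' Male-to-female ratio at printed precision
#'
#' @param male,female Counts; `female` must be positive.
#' @return Ratio rounded half-up to 3 decimals.
#' @examples
#' sex_ratio(140, 155) # 0.903
#' @export
sex_ratio <- function(male, female) {
  if (any(female <= 0)) stop("sex ratio undefined for female = 0", call. = FALSE)
  round_half_up(male / female, 3)
}

#' Age binning schemes
#'
#' Closed-interval age bins as used by the two databases' public summaries:
#' the aggregate interface splits the elderly into 65-74 and >= 75, while
#' FAERS-style tables use a single >= 65 bin.
#'
#' @return A named list of `c(lower, upper)` closed intervals in years.
#' @export
age_bins_vigiaccess <- function() {
  list("<18" = c(0, 17), "18-44" = c(18, 44), "45-64" = c(45, 64),
       "65-74" = c(65, 74), ">=75" = c(75, Inf))
}

#' @rdname age_bins_vigiaccess
#' @export
age_bins_faers <- function() {
  list("<18" = c(0, 17), "18-44" = c(18, 44), "45-64" = c(45, 64),
       ">=65" = c(65, Inf))
}

bin_ages <- function(age_years, bins) {
  out <- rep("unknown", length(age_years))
  for (lab in names(bins)) {
    lo <- bins[[lab]][1]; hi <- bins[[lab]][2]
    sel <- !is.na(age_years) & age_years >= lo & age_years <= hi
    out[sel] <- lab
  }
  out
}

#' Map ISO-like country codes to continents
#'
#' Uses the bundled static country-to-continent table; unmapped codes return
#' `"unknown"`.
#'
#' @param country Character vector of country codes.
#' @return Character vector of continent names.
#' @export
country_to_continent <- function(country) {
  map <- readr::read_csv(
    system.file("extdata", "country_continent.csv", package = "pvsignal"),
    col_types = "cc", progress = FALSE
  )
  idx <- match(toupper(trimws(country)), map$country)
  out <- map$continent[idx]
  out[is.na(out)] <- "unknown"
  out
}

#' Baseline characterization table for one category
#'
#' Counts and percentages over the strata of one demographic category, with
#' all missing values in an explicit `"unknown"` stratum so counts always sum
#' to the cohort size. Percent denominators are the cohort size and use the
#' printed 2-decimal half-up convention.
#'
#' @param reports Report tibble from [link_reports()].
#' @param category One of `"sex"`, `"age_group"`, `"year"`, `"region"`,
#'   `"reporter"`, `"seriousness"`.
#' @param age_bins Binning scheme for `age_group` (see [age_bins_faers()]).
#' @return Tibble with columns `category`, `stratum`, `count`, `percent`.
#' @export
baseline_table <- function(reports, category, age_bins = age_bins_faers()) {
  categories <- c("sex", "age_group", "year", "region", "reporter", "seriousness")
  if (!category %in% categories) {
    stop("unknown category '", category, "'; must be one of ",
         paste(categories, collapse = ", "), call. = FALSE)
  }
  if (nrow(reports) == 0) stop("empty cohort", call. = FALSE)
  stratum <- switch(
    category,
    sex = dplyr::recode(reports$sex, F = "female", M = "male",
                        .missing = "unknown"),
    age_group = bin_ages(reports$age_years, age_bins),
    year = ifelse(is.na(reports$report_year), "unknown",
                  as.character(reports$report_year)),
    region = country_to_continent(reports$country),
    reporter = ifelse(is.na(reports$reporter), "unknown", reports$reporter),
    seriousness = ifelse(reports$serious, "serious", "non-serious")
  )
  total <- nrow(reports)
  tibble::tibble(stratum = stratum) |>
    dplyr::count(.data$stratum, name = "count") |>
    dplyr::mutate(category = category,
                  percent = percentage(.data$count, total)) |>
    dplyr::select("category", "stratum", "count", "percent")
}

#' Baseline table from an aggregate-only count table
#'
#' Aggregate public interfaces expose only per-category counts; this derives
#' the same (stratum, count, percent) layout from them, using the category's
#' own total as denominator.
#'
#' @param agg Tibble with columns `category`, `stratum`, `count`.
#' @param category Category to extract.
#' @return Tibble with columns `category`, `stratum`, `count`, `percent`.
#' @export
baseline_from_aggregate <- function(agg, category) {
  rows <- agg[agg$category == category, ]
  if (nrow(rows) == 0) stop("category '", category, "' not present", call. = FALSE)
  total <- sum(rows$count)
  dplyr::mutate(rows, percent = percentage(.data$count, total))
}
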