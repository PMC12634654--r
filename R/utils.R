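#' Round half away from zero at a fixed number of decimals
#'
#' Base [round()] uses round-half-to-even; published pharmacovigilance tables
#' (percentages to 2 decimals, ratios to 3) conventionally round halves up.
#' This helper reproduces that convention for non-negative inputs.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(2.345, 2) # 2.35, where round() gives 2.34
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 guard absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Normalize a term for dictionary-style matching
#'
#' Trims, collapses internal whitespace, and upper-cases. Used for drug-name
#' and MedDRA preferred-term matching throughout the package.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  toupper(gsub("\\s+", " ", trimws(as.character(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared column-name constants for the FAERS-dialect tables
faers_schemas <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX", "AGE",
           "AGE_COD", "REPORTER_COUNTRY", "OCCP_COD"),
  drug = c("PRIMARYID", "DRUG_SEQ", "DRUGNAME", "ROLE_COD"),
  reac = c("PRIMARYID", "PT"),
  ther = c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT", "END_DT"),
  outc = c("PRIMARYID", "OUTC_COD")
)

utils::globalVariables(c(
  ".data", "a", "b", "c_", "caseid", "cohort", "count", "cum_percent", "d",
  "day", "days", "drugname", "ebgm05", "event", "fda_dt", "ic025", "level",
  "month", "n", "percent", "primaryid", "prr", "pt", "role_cod", "ror",
  "ror_high", "ror_low", "sex", "soc", "start_dt", "stratum", "chi2",
  "ebgm", "ic", "signal", "E", "N"
))
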