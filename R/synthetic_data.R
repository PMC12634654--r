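#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a simulated spontaneous reporting system snapshot: a number of
#' case reports, a drug vocabulary with one target drug, a preferred-term (PT)
#' event vocabulary, planted drug-event associations with known relative
#' risks, injected duplicate reports, configurable missingness, and
#' Weibull-distributed onset times. Every downstream stage of the package can
#' therefore be tested against known ground truth.
#'
#' Event assignment is independent Bernoulli per PT given the report's primary
#' suspect drug: background PTs occur with probability `background_event_prob`
#' regardless of drug, while a planted pair's probability given the target
#' drug is multiplied by its relative risk. Onset is drawn from
#' `Weibull(onset_shape, onset_scale)` in days and added to the therapy start
#' date. Duplicates re-report an existing case (same CASEID) with a later
#' FDA receipt date and a larger PRIMARYID, so the expected deduplication
#' survivor is known by construction.
#'
#' @param n_reports Number of distinct case reports (before duplicates).
#' @param n_background_drugs Size of the non-target drug vocabulary.
#' @param n_background_events Number of background PTs (drawn from the bundled
#'   MedDRA-style stub so SOC aggregation works out of the box).
#' @param target_drug Name of the drug of interest.
#' @param planted_signals Data frame with columns `pt` and `rr`: PTs whose
#'   event probability given the target drug is multiplied by `rr` (>= 0).
#' @param drug_prob Probability a report's primary suspect is the target drug.
#' @param background_event_prob Per-PT background event probability.
#' @param duplicate_rate Fraction of reports re-reported as duplicates.
#' @param missing_age_rate,missing_sex_rate,missing_ther_date_rate Fractions
#'   of reports with the corresponding field blanked.
#' @param partial_date_rate Fraction of event dates truncated to YYYYMM or
#'   YYYY (half each), to stress the partial-date policy.
#' @param onset_shape,onset_scale Weibull shape (dimensionless) and scale
#'   (days) of the onset-time distribution.
#' @param sex_split Fraction of reports that are female (before missingness).
#' @param serious_rate Probability a report carries an outcome row (serious).
#' @param date_range Length-2 `Date` vector bounding therapy start dates.
#' @param seed Integer RNG seed; identical seeds give identical bundles.
#' @return A `pv_synthetic_config` list.
#' @seealso [generate_bundle()], [make_vigiaccess_aggregate()]
#' @export
synthetic_config <- function(n_reports = 2000,
                             n_background_drugs = 20,
                             n_background_events = 50,
                             target_drug = "FENOFIBRIC ACID",
                             planted_signals = default_planted_signals(),
                             drug_prob = 0.10,
                             background_event_prob = 0.04,
                             duplicate_rate = 0.05,
                             missing_age_rate = 0.20,
                             missing_sex_rate = 0.10,
                             missing_ther_date_rate = 0.30,
                             partial_date_rate = 0,
                             onset_shape = 0.68,
                             onset_scale = 45,
                             sex_split = 0.5,
                             serious_rate = 0.17,
                             date_range = as.Date(c("2004-01-01", "2024-09-30")),
                             seed = 1L) {
  stopifnot(
    n_reports >= 1, n_background_drugs >= 1, n_background_events >= 1,
    onset_shape > 0, onset_scale > 0
  )
  fracs <- c(drug_prob, background_event_prob, duplicate_rate,
             missing_age_rate, missing_sex_rate, missing_ther_date_rate,
             partial_date_rate, sex_split, serious_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all rate/fraction parameters must lie in [0, 1]", call. = FALSE)
  }
  planted_signals <- tibble::as_tibble(planted_signals)
  if (nrow(planted_signals) > 0) {
    stopifnot(all(c("pt", "rr") %in% names(planted_signals)))
    if (any(planted_signals$rr < 0)) {
      stop("planted relative risks must be >= 0", call. = FALSE)
    }
    planted_signals$pt <- normalize_term(planted_signals$pt)
  }
  date_range <- as.Date(date_range)
  stopifnot(length(date_range) == 2, date_range[1] <= date_range[2])
  structure(
    list(
      n_reports = as.integer(n_reports),
      n_background_drugs = as.integer(n_background_drugs),
      n_background_events = as.integer(n_background_events),
      target_drug = normalize_term(target_drug),
      planted_signals = planted_signals,
      drug_prob = drug_prob,
      background_event_prob = background_event_prob,
      duplicate_rate = duplicate_rate,
      missing_age_rate = missing_age_rate,
      missing_sex_rate = missing_sex_rate,
      missing_ther_date_rate = missing_ther_date_rate,
      partial_date_rate = partial_date_rate,
      onset_shape = onset_shape,
      onset_scale = onset_scale,
      sex_split = sex_split,
      serious_rate = serious_rate,
      date_range = date_range,
      seed = as.integer(seed)
    ),
    class = "pv_synthetic_config"
  )
}

#' Default planted drug-event associations
#'
#' Three PTs from the bundled dictionary stub with strong, moderate, and weak
#' relative risks, emulating the mix of signal strengths a real
#' disproportionality screen returns.
#'
#' @return Tibble with columns `pt` and `rr`.
#' @export
default_planted_signals <- function() {
  tibble::tibble(
    pt = c("MYALGIA", "BLOOD CREATINE PHOSPHOKINASE INCREASED", "GOUT"),
    rr = c(8, 5, 3)
  )
}

fmt_ymd <- function(d) {
  lt <- as.POSIXlt(d)
  sprintf("%04d%02d%02d", lt$year + 1900L, lt$mon + 1L, lt$mday)
}

#' Generate a synthetic FAERS-dialect report bundle
#'
#' Draws a full set of DEMO / DRUG / REAC / THER / OUTC tables plus a
#' ground-truth manifest from a [synthetic_config()]. Each report carries one
#' primary-suspect drug row (the target with probability `drug_prob`) and, in
#' about a third of reports, one concomitant drug row; events are independent
#' Bernoulli per PT with planted pairs boosted by their relative risk; the
#' event date is therapy start plus a Weibull onset draw rounded to whole
#' days. Duplicates are appended as later re-reports of existing CASEIDs with
#' larger PRIMARYIDs, and the manifest records the expected deduplication
#' survivor of every duplicated case.
#'
#' @param config A [synthetic_config()].
#' @return A `pv_bundle`: list with tibbles `demo`, `drug`, `reac`, `ther`,
#'   `outc` and a `manifest` list (`planted`, `duplicates`, `target_drug`,
#'   `n_reports`).
#' @examples
#' b <- generate_bundle(synthetic_config(n_reports = 200, seed = 7))
#' nrow(b$demo)
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "pv_synthetic_config"))
  q <- config$background_event_prob
  planted <- config$planted_signals
  if (nrow(planted) > 0 && any(q * planted$rr > 1)) {
    bad <- planted$pt[q * planted$rr > 1]
    stop("planted relative risk makes event probability exceed 1 for: ",
         paste(bad, collapse = ", "),
         " (background_event_prob * rr must be <= 1)", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_reports

  events <- synthetic_event_vocabulary(config)
  drugs_bg <- sprintf("BACKGROUND DRUG %02d", seq_len(config$n_background_drugs))

  primaryid <- as.character(100000000 + seq_len(n))
  caseid <- as.character(20000000 + seq_len(n))

  span <- as.integer(config$date_range[2] - config$date_range[1])
  ther_start <- config$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  onset_days <- round(stats::rweibull(n, shape = config$onset_shape,
                                      scale = config$onset_scale))
  event_date <- ther_start + onset_days
  # receipt lags reporting of the event by days-to-weeks
  fda_date <- event_date + stats::rpois(n, 20)

  sex <- ifelse(stats::runif(n) < config$sex_split, "F", "M")
  sex[stats::runif(n) < config$missing_sex_rate] <- NA_character_
  age <- pmin(pmax(round(stats::rnorm(n, 60, 15)), 1), 95)
  age[stats::runif(n) < config$missing_age_rate] <- NA_real_
  country <- sample(c("US", "JP", "FR", "CN", "GB", "BR", "IN", "CA"), n,
                    replace = TRUE,
                    prob = c(0.45, 0.12, 0.08, 0.12, 0.06, 0.05, 0.06, 0.06))
  occp <- sample(c("MD", "CN", "PH", "OT"), n, replace = TRUE,
                 prob = c(0.45, 0.30, 0.15, 0.10))

  event_dt <- fmt_ymd(event_date)
  if (config$partial_date_rate > 0) {
    trunc_idx <- which(stats::runif(n) < config$partial_date_rate)
    half <- seq_along(trunc_idx) %% 2 == 0
    event_dt[trunc_idx[half]] <- substr(event_dt[trunc_idx[half]], 1, 6)
    event_dt[trunc_idx[!half]] <- substr(event_dt[trunc_idx[!half]], 1, 4)
  }

  demo <- tibble::tibble(
    PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fmt_ymd(fda_date),
    EVENT_DT = event_dt, SEX = sex, AGE = age,
    AGE_COD = ifelse(is.na(age), NA_character_, "YR"),
    REPORTER_COUNTRY = country, OCCP_COD = occp
  )

  is_target <- stats::runif(n) < config$drug_prob
  ps_name <- ifelse(is_target, config$target_drug,
                    sample(drugs_bg, n, replace = TRUE))
  drug <- tibble::tibble(
    PRIMARYID = primaryid, DRUG_SEQ = "1", DRUGNAME = ps_name, ROLE_COD = "PS"
  )
  # concomitant rows exercise the role-code filter; they may name the target
  has_conc <- stats::runif(n) < 0.3
  conc <- tibble::tibble(
    PRIMARYID = primaryid[has_conc], DRUG_SEQ = "2",
    DRUGNAME = sample(c(drugs_bg, config$target_drug), sum(has_conc),
                      replace = TRUE),
    ROLE_COD = "C"
  )
  drug <- dplyr::bind_rows(drug, conc)

  prob <- matrix(q, nrow = n, ncol = length(events),
                 dimnames = list(NULL, events))
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      prob[is_target, planted$pt[i]] <- q * planted$rr[i]
    }
  }
  hit <- matrix(stats::runif(n * length(events)), n) < prob
  # guarantee at least one reaction per report with a drug-independent
  # uniform PT so 2x2 association structure is not distorted
  none <- !matrixStats_rowAnys(hit)
  filler_pt <- sample(events, sum(none), replace = TRUE)
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1]), , drop = FALSE]
  reac <- tibble::tibble(
    PRIMARYID = c(primaryid[idx[, 1]], primaryid[none]),
    PT = c(colnames(prob)[idx[, 2]], filler_pt)
  )
  reac <- dplyr::arrange(reac, .data$PRIMARYID, .data$PT)

  start_dt <- fmt_ymd(ther_start)
  start_dt[stats::runif(n) < config$missing_ther_date_rate] <- NA_character_
  ther <- tibble::tibble(
    PRIMARYID = primaryid, DSG_DRUG_SEQ = "1", START_DT = start_dt,
    END_DT = NA_character_
  )

  serious <- stats::runif(n) < config$serious_rate
  outc <- tibble::tibble(
    PRIMARYID = primaryid[serious],
    OUTC_COD = sample(c("HO", "OT", "DE", "LT", "DS"), sum(serious),
                      replace = TRUE, prob = c(0.5, 0.25, 0.1, 0.1, 0.05))
  )

  # duplicate injection: later FDA_DT re-report of an existing case with a
  # larger PRIMARYID; child rows are carried over verbatim
  n_dup <- round(config$duplicate_rate * n)
  duplicates <- tibble::tibble(caseid = character(), original_primaryid = character(),
                               duplicate_primaryid = character(),
                               survivor_primaryid = character())
  if (n_dup > 0) {
    dup_of <- sample.int(n, n_dup)
    dup_pid <- as.character(100000000 + n + seq_len(n_dup))
    dup_demo <- demo[dup_of, ]
    dup_demo$PRIMARYID <- dup_pid
    dup_demo$FDA_DT <- fmt_ymd(fda_date[dup_of] + sample(5:120, n_dup, replace = TRUE))
    demo <- dplyr::bind_rows(demo, dup_demo)
    copy_children <- function(tab) {
      idx <- match(tab$PRIMARYID, primaryid[dup_of])
      kid <- tab[!is.na(idx), ]
      kid$PRIMARYID <- dup_pid[idx[!is.na(idx)]]
      dplyr::bind_rows(tab, kid)
    }
    drug <- copy_children(drug); reac <- copy_children(reac)
    ther <- copy_children(ther); outc <- copy_children(outc)
    duplicates <- tibble::tibble(
      caseid = caseid[dup_of], original_primaryid = primaryid[dup_of],
      duplicate_primaryid = dup_pid,
      survivor_primaryid = dup_pid # later FDA_DT always wins by construction
    )
  }

  structure(
    list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
         manifest = list(planted = planted, duplicates = duplicates,
                         target_drug = config$target_drug,
                         n_reports = n, config = config)),
    class = "pv_bundle"
  )
}

# rowAnys without a matrixStats dependency
matrixStats_rowAnys <- function(m) rowSums(m) > 0

synthetic_event_vocabulary <- function(config) {
  stub <- load_meddra()
  pts <- stub$pt
  k <- min(config$n_background_events, length(pts))
  events <- pts[seq_len(k)]
  if (config$n_background_events > length(pts)) {
    events <- c(events, sprintf("SYNTHETIC EVENT %03d",
                                seq_len(config$n_background_events - length(pts))))
  }
  unique(c(events, config$planted_signals$pt))
}

#' @export
print.pv_bundle <- function(x, ...) {
  cat("<pv_bundle>", nrow(x$demo), "DEMO rows |", nrow(x$reac), "REAC rows |",
      nrow(x$drug), "DRUG rows\n")
  cat("  target drug:", x$manifest$target_drug, "|",
      nrow(x$manifest$planted), "planted signal(s) |",
      nrow(x$manifest$duplicates), "injected duplicate(s)\n")
  invisible(x)
}

#' Write a bundle as FAERS-dialect quarterly ASCII files
#'
#' One `"$"`-delimited text file per table with an uppercase header row and
#' quarterly naming (e.g. `DEMO24Q3.txt`), plus the ground-truth manifest as
#' `manifest.json`. Missing fields become empty strings between delimiters
#' and read back as missing, so the bundle round-trips losslessly through
#' [read_faers_table()].
#'
#' @param bundle A `pv_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @param quarter Quarter tag used in file names, e.g. `"24Q3"`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_faers_dialect <- function(bundle, dir, quarter = "24Q3") {
  stopifnot(inherits(bundle, "pv_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (kind in c("demo", "drug", "reac", "ther", "outc")) {
    path <- file.path(dir, paste0(toupper(kind), quarter, ".txt"))
    readr::write_delim(bundle[[kind]], path, delim = "$", na = "")
    paths[kind] <- path
  }
  manifest <- bundle$manifest
  manifest$config <- unclass(manifest$config)
  manifest$config$date_range <- as.character(manifest$config$date_range)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths["manifest"] <- file.path(dir, "manifest.json")
  invisible(paths)
}

#' Build a VigiAccess-style aggregate count table
#'
#' Public aggregate interfaces expose only per-category statistical
#' distributions (sex, age group, reporting year, region), never case-level
#' records. This emulates that: it draws `n_reports` reports under the
#' config's demographic model and returns counts per (category, stratum),
#' with an `"unknown"` stratum absorbing missingness, so within each category
#' the counts sum to `n_reports`.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `category`, `stratum`, `count`.
#' @export
make_vigiaccess_aggregate <- function(config) {
  stopifnot(inherits(config, "pv_synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_reports
  sex <- ifelse(stats::runif(n) < config$sex_split, "female", "male")
  sex[stats::runif(n) < config$missing_sex_rate] <- "unknown"
  age <- pmin(pmax(round(stats::rnorm(n, 60, 15)), 1), 95)
  age[stats::runif(n) < config$missing_age_rate] <- NA_real_
  age_group <- bin_ages(age, age_bins_vigiaccess())
  span <- as.integer(config$date_range[2] - config$date_range[1])
  yr <- format(config$date_range[1] +
                 sample.int(span + 1L, n, replace = TRUE) - 1L, "%Y")
  country <- sample(c("US", "JP", "FR", "CN", "GB", "BR", "IN", "CA"), n,
                    replace = TRUE,
                    prob = c(0.45, 0.12, 0.08, 0.12, 0.06, 0.05, 0.06, 0.06))
  region <- country_to_continent(country)
  long <- dplyr::bind_rows(
    tibble::tibble(category = "sex", stratum = sex),
    tibble::tibble(category = "age_group", stratum = age_group),
    tibble::tibble(category = "year", stratum = yr),
    tibble::tibble(category = "region", stratum = region)
  )
  dplyr::count(long, .data$category, .data$stratum, name = "count")
}
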