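#' Read one FAERS-dialect quarterly table
#'
#' FAERS quarterly ASCII files are `"$"`-delimited with an uppercase header
#' row. All fields are read as character; empty fields become `NA`. The
#' header must contain the expected columns for the table kind
#' (case-insensitive); extra columns are preserved untouched. Lines whose
#' field count cannot be parsed are skipped, and the number skipped is
#' attached as the `n_skipped` attribute.
#'
#' @param path Path to the file.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`.
#' @return Tibble with upper-case column names and an `n_skipped` attribute.
#' @export
read_faers_table <- function(path, kind = c("demo", "drug", "reac", "ther", "outc")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- suppressWarnings(readr::read_delim(
    path, delim = "$", col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  ))
  names(tab) <- toupper(trimws(names(tab)))
  required <- faers_schemas[[kind]]
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed ", toupper(kind), " header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(tab)
  n_skipped <- 0L
  if (nrow(probs) > 0) {
    bad_rows <- unique(probs$row)
    tab <- tab[-bad_rows, , drop = FALSE]
    n_skipped <- length(bad_rows)
    message("read_faers_table: skipped ", n_skipped, " unparseable line(s) in ",
            basename(path))
  }
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Read a directory of FAERS-dialect quarterly files
#'
#' Locates `DEMO*`, `DRUG*`, `REAC*`, `THER*`, `OUTC*` text files (one or more
#' quarters each) and row-binds per kind.
#'
#' @param dir Directory containing the quarterly files.
#' @return Named list of tibbles `demo`, `drug`, `reac`, `ther`, `outc`.
#' @export
read_faers_bundle <- function(dir) {
  out <- list()
  for (kind in c("demo", "drug", "reac", "ther", "outc")) {
    files <- list.files(dir, pattern = paste0("^", toupper(kind), ".*\\.txt$"),
                        full.names = TRUE)
    if (length(files) == 0) stop("no ", toupper(kind), " file found in ", dir,
                                 call. = FALSE)
    out[[kind]] <- dplyr::bind_rows(lapply(files, read_faers_table, kind = kind))
  }
  out
}

#' Parse possibly-partial FAERS dates
#'
#' FAERS date fields carry 8 (YYYYMMDD), 6 (YYYYMM) or 4 (YYYY) digits.
#' 8 digits parse exactly; 6 digits are imputed to the first day of the month
#' (tolerable for monthly onset binning); 4 digits cannot place a month and
#' yield `NA` here — use [partial_date_year()] to recover the year for annual
#' tabulation. Anything else is `NA`.
#'
#' @param x Character vector of date fields.
#' @return `Date` vector.
#' @examples
#' parse_partial_date(c("20200310", "202003", "2020", ""))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  ym <- grepl("^\\d{6}$", x)
  out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  out
}

#' Extract the year from a possibly-partial FAERS date
#'
#' @param x Character vector of 4/6/8-digit date fields.
#' @return Integer vector of years (`NA` where no 4-digit prefix exists).
#' @export
partial_date_year <- function(x) {
  x <- trimws(as.character(x))
  ok <- !is.na(x) & grepl("^\\d{4}", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(substr(x[ok], 1, 4))
  out
}

#' Deduplicate DEMO records by the FDA rule
#'
#' For records sharing a CASEID only the report with the most recent FDA
#' receipt date (FDA_DT) is retained; among FDA_DT ties the largest PRIMARYID
#' wins. The result has exactly one row per CASEID and is sorted by CASEID,
#' so the operation is deterministic and idempotent.
#'
#' @param demo DEMO tibble with `PRIMARYID`, `CASEID`, `FDA_DT` columns.
#' @return Deduplicated DEMO tibble sorted by CASEID.
#' @export
deduplicate_demo <- function(demo) {
  stopifnot(all(c("PRIMARYID", "CASEID", "FDA_DT") %in% names(demo)))
  pid_num <- suppressWarnings(as.numeric(demo$PRIMARYID))
  # numeric comparison of PRIMARYID where possible, lexicographic fallback
  pid_rank <- if (anyNA(pid_num)) rank(demo$PRIMARYID) else pid_num
  demo |>
    dplyr::mutate(.pid_rank = pid_rank) |>
    dplyr::arrange(.data$CASEID, dplyr::desc(.data$FDA_DT),
                   dplyr::desc(.data$.pid_rank)) |>
    dplyr::distinct(.data$CASEID, .keep_all = TRUE) |>
    dplyr::select(-".pid_rank")
}

#' Link deduplicated DEMO records into case-level safety reports
#'
#' Joins the child tables on PRIMARYID. Reports without any reaction row are
#' dropped (their count is attached as `n_dropped_no_reaction`); orphan child
#' rows without a surviving DEMO parent are ignored. `therapy_start` is the
#' earliest parseable start date among THER rows belonging to a drug row
#' matching `drug_names`; `serious` is `TRUE` exactly when the report has at
#' least one outcome row.
#'
#' @param demo Deduplicated DEMO tibble (see [deduplicate_demo()]).
#' @param drug,reac,ther,outc The child tibbles.
#' @param drug_names Character vector of target drug names (normalized
#'   matching) used to select the therapy rows that define `therapy_start`.
#' @return Tibble of safety reports, one row per case, with list-columns
#'   `drug_names` and `drug_roles` (parallel character vectors, one entry per
#'   drug row), `reactions` (character vectors of PTs) and `outcomes`, scalar
#'   columns for demographics, `event_date`, `therapy_start`, `serious`.
#' @export
link_reports <- function(demo, drug, reac, ther, outc, drug_names) {
  stopifnot(length(drug_names) >= 1)
  targets <- normalize_term(drug_names)
  pid <- demo$PRIMARYID

  reac_kept <- reac[reac$PRIMARYID %in% pid & !is.na(reac$PT), ]
  fpid <- factor(reac_kept$PRIMARYID, levels = pid)
  reactions <- split(normalize_term(reac_kept$PT), fpid)

  drug_kept <- drug[drug$PRIMARYID %in% pid, ]
  drug_kept$DRUGNAME <- normalize_term(drug_kept$DRUGNAME)
  fdrug <- factor(drug_kept$PRIMARYID, levels = pid)
  drug_names_col <- split(drug_kept$DRUGNAME, fdrug)
  drug_roles_col <- split(drug_kept$ROLE_COD, fdrug)

  outc_kept <- outc[outc$PRIMARYID %in% pid & !is.na(outc$OUTC_COD), ]
  outcomes <- split(outc_kept$OUTC_COD, factor(outc_kept$PRIMARYID, levels = pid))

  # therapy rows attached to a target-drug DRUG row (matched on primaryid+seq)
  ther_kept <- ther[ther$PRIMARYID %in% pid, ]
  seq_col <- if ("DSG_DRUG_SEQ" %in% names(ther_kept)) "DSG_DRUG_SEQ" else "DRUG_SEQ"
  key_ther <- paste(ther_kept$PRIMARYID, ther_kept[[seq_col]])
  key_drug <- paste(drug_kept$PRIMARYID, drug_kept$DRUG_SEQ)
  is_target_row <- drug_kept$DRUGNAME %in% targets
  ther_target <- ther_kept[key_ther %in% key_drug[is_target_row], ]
  ther_target$start <- parse_partial_date(ther_target$START_DT)
  ther_target <- ther_target[!is.na(ther_target$start), ]
  starts <- if (nrow(ther_target) == 0) {
    tibble::tibble(PRIMARYID = character(), therapy_start = as.Date(character()))
  } else {
    ther_target |>
      dplyr::group_by(.data$PRIMARYID) |>
      dplyr::summarise(therapy_start = min(.data$start), .groups = "drop")
  }

  reports <- tibble::tibble(
    primaryid = pid,
    caseid = demo$CASEID,
    fda_date = parse_partial_date(demo$FDA_DT),
    event_date = parse_partial_date(demo$EVENT_DT),
    event_year = partial_date_year(demo$EVENT_DT),
    report_year = partial_date_year(demo$FDA_DT),
    sex = {
      s <- toupper(trimws(demo$SEX))
      ifelse(!is.na(s) & s %in% c("F", "M"), s, NA_character_)
    },
    age_years = age_to_years(demo$AGE, demo$AGE_COD),
    country = toupper(trimws(demo$REPORTER_COUNTRY)),
    reporter = demo$OCCP_COD,
    drug_names = unname(drug_names_col),
    drug_roles = unname(drug_roles_col),
    reactions = unname(reactions),
    outcomes = unname(outcomes)
  )
  reports$therapy_start <- starts$therapy_start[match(pid, starts$PRIMARYID)]
  reports$serious <- lengths(reports$outcomes) > 0

  no_reac <- lengths(reports$reactions) == 0
  out <- reports[!no_reac, ]
  attr(out, "n_dropped_no_reaction") <- sum(no_reac)
  if (sum(no_reac) > 0) {
    message("link_reports: dropped ", sum(no_reac), " report(s) without reactions")
  }
  out
}

#' Convert FAERS age fields to years
#'
#' Handles the DEC/YR/MON/WK/DY/HR unit codes; unparseable values stay `NA`
#' and land in the "unknown" stratum downstream.
#'
#' @param age Character or numeric vector of ages.
#' @param age_cod Character vector of unit codes.
#' @return Numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  unit[unit == ""] <- "YR"
  lookup <- c(DEC = 10, YR = 1, YEAR = 1, MON = 1 / 12, MO = 1 / 12,
              WK = 1 / 52.143, DY = 1 / 365.25, HR = 1 / 8766)
  a * unname(lookup[unit])
}

#' Split reports into the primary-suspect cohort and the background
#'
#' A report enters the cohort when at least one of its drug rows names a
#' target drug (after trim/collapse/upper-case normalization, optionally
#' extended with synonyms) with the primary-suspect role code. Everything
#' else is background, so the two pieces partition the input.
#'
#' @param reports Report tibble from [link_reports()].
#' @param drug_names Character vector of names identifying the target drug.
#' @param role_code Role code(s) that qualify; default `"PS"`.
#' @return List with tibbles `cohort` and `background`.
#' @export
primary_suspect_cohort <- function(reports, drug_names, role_code = "PS") {
  stopifnot(length(drug_names) >= 1)
  targets <- normalize_term(drug_names)
  long_pid <- rep(reports$primaryid, lengths(reports$drug_names))
  long_name <- unlist(reports$drug_names, use.names = FALSE)
  long_role <- unlist(reports$drug_roles, use.names = FALSE)
  hit_pid <- unique(long_pid[long_name %in% targets & long_role %in% role_code])
  in_cohort <- reports$primaryid %in% hit_pid
  list(cohort = reports[in_cohort, ], background = reports[!in_cohort, ])
}
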