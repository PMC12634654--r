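#' Load a preferred-term to system-organ-class dictionary
#'
#' Reads a CSV with columns `pt`, `pt_code`, `soc`, `soc_code` into a
#' normalized lookup (trimmed, upper-cased PT keys). The package bundles a
#' small demonstration stub covering common adverse-event PTs; the full
#' licensed MedDRA hierarchy is deliberately out of scope and any
#' appropriately formatted dictionary can be supplied instead.
#'
#' Duplicate rows that agree on the SOC collapse to one entry; duplicates
#' that disagree are an error, because each PT must have exactly one primary
#' SOC.
#'
#' @param path CSV path; `NULL` loads the bundled stub.
#' @return A `pv_meddra` tibble with columns `pt`, `pt_code`, `soc`,
#'   `soc_code` (PT keys normalized and unique).
#' @export
load_meddra <- function(path = NULL) {
  path <- path %||% system.file("extdata", "meddra_stub.csv", package = "pvsignal")
  dict <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  required <- c("pt", "pt_code", "soc", "soc_code")
  missing_cols <- setdiff(required, names(dict))
  if (length(missing_cols) > 0) {
    stop("dictionary is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dict$pt <- normalize_term(dict$pt)
  dict$soc <- trimws(dict$soc)
  dict <- dplyr::distinct(dict)
  dup <- dict$pt[duplicated(dict$pt)]
  if (length(dup) > 0) {
    stop("conflicting SOC assignment for PT(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  class(dict) <- c("pv_meddra", class(dict))
  dict
}

#' Map preferred terms to system organ classes
#'
#' Case-insensitive lookup; PTs absent from the dictionary map to the
#' explicit `"unmapped"` bucket (counted via the `n_unmapped` attribute) so
#' SOC-level totals remain a partition of the PT-level totals.
#'
#' @param dictionary A `pv_meddra` from [load_meddra()].
#' @param pt Character vector of preferred terms.
#' @return Character vector of SOC names with an `n_unmapped` attribute.
#' @export
pt_to_soc <- function(dictionary, pt) {
  stopifnot(inherits(dictionary, "pv_meddra"))
  idx <- match(normalize_term(pt), dictionary$pt)
  out <- dictionary$soc[idx]
  out[is.na(out)] <- "unmapped"
  attr(out, "n_unmapped") <- sum(is.na(idx))
  out
}
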