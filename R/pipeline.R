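#' Assemble a pipeline run configuration
#'
#' A run is driven either by a directory of FAERS-dialect quarterly files or
#' by a [synthetic_config()] (in which case the bundle is generated on the
#' fly). All analysis knobs live here: target drug synonyms, the qualifying
#' role code, the dictionary path, the age-bin scheme, the six signal-rule
#' thresholds, and the information-component variant.
#'
#' @param input_dir Directory of quarterly files, or `NULL` when `synthetic`
#'   is given.
#' @param synthetic Optional [synthetic_config()].
#' @param drug_names Target drug name(s)/synonyms.
#' @param role_code Qualifying drug role code(s); default primary suspect.
#' @param dictionary_path PT-to-SOC dictionary CSV (`NULL` = bundled stub).
#' @param age_bins `"faers"` or `"vigiaccess"` binning scheme.
#' @param thresholds [signal_thresholds()] list.
#' @param ic_method `"closed_form"` or `"shrinkage"` (see [bcpnn_ic()]).
#' @param out_dir Optional output directory for exported tables.
#' @param seed Integer seed controlling any randomness in the run.
#' @return A `pv_run_config` list.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL,
                       drug_names = "FENOFIBRIC ACID", role_code = "PS",
                       dictionary_path = NULL, age_bins = c("faers", "vigiaccess"),
                       thresholds = signal_thresholds(),
                       ic_method = c("closed_form", "shrinkage"),
                       out_dir = NULL, seed = 1L) {
  age_bins <- match.arg(age_bins)
  ic_method <- match.arg(ic_method)
  if (is.null(input_dir) && is.null(synthetic)) {
    stop("either input_dir or a synthetic config is required", call. = FALSE)
  }
  if (!is.null(dictionary_path) && !file.exists(dictionary_path)) {
    stop("dictionary not found: ", dictionary_path, call. = FALSE)
  }
  stopifnot(all(unlist(thresholds) >= 0))
  structure(
    list(input_dir = input_dir, synthetic = synthetic,
         drug_names = drug_names, role_code = role_code,
         dictionary_path = dictionary_path, age_bins = age_bins,
         thresholds = thresholds, ic_method = ic_method,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pv_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (`synthetic` may be a mapping of [synthetic_config()] arguments,
#'   `thresholds` a mapping of [signal_thresholds()] arguments).
#' @return A `pv_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(signal_thresholds, raw$thresholds)
  }
  do.call(run_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or synthetic generation), deduplication, linkage,
#' cohort extraction, baseline tables, PT- and SOC-level signal detection,
#' time-to-onset modelling, and the sex-stratified onset comparison. Every
#' exclusion is counted in the funnel, stage errors are re-raised with the
#' stage name, and the run is a pure function of the configuration, so
#' identical seeds give identical results.
#'
#' @param config A `pv_run_config` from [run_config()].
#' @return A `pv_run_report` list: `funnel`, `baseline`, `signals_pt`,
#'   `signals_soc`, `tto` (sample, histogram, fit, curve, median CI),
#'   `sex_comparison`, plus the bundle manifest for synthetic runs. Tables
#'   are also exported when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_run_config"))
  tables <- with_stage("ingest", {
    if (!is.null(config$synthetic)) {
      bundle <- generate_bundle(config$synthetic)
      bundle[c("demo", "drug", "reac", "ther", "outc")] |>
        c(list(manifest = bundle$manifest))
    } else {
      read_faers_bundle(config$input_dir)
    }
  })
  dictionary <- with_stage("dictionary", load_meddra(config$dictionary_path))

  n_raw <- nrow(tables$demo)
  demo <- with_stage("deduplicate", deduplicate_demo(tables$demo))
  reports <- with_stage("link", link_reports(
    demo, tables$drug, tables$reac, tables$ther, tables$outc,
    drug_names = config$drug_names
  ))
  split <- with_stage("cohort", primary_suspect_cohort(
    reports, config$drug_names, role_code = config$role_code
  ))
  if (nrow(split$cohort) == 0) {
    stop("[stage: cohort] no reports match the target drug", call. = FALSE)
  }

  bins <- if (config$age_bins == "faers") age_bins_faers() else age_bins_vigiaccess()
  baseline <- with_stage("describe", dplyr::bind_rows(lapply(
    c("sex", "age_group", "year", "region", "reporter", "seriousness"),
    function(cat) baseline_table(split$cohort, cat, age_bins = bins)
  )))

  signals_pt <- with_stage("signals_pt", signal_stats(
    build_contingency(split$cohort, split$background, level = "PT"),
    ic_method = config$ic_method, thresholds = config$thresholds
  ))
  # the shrinkage prior is estimated once on the full PT-level database and
  # reused at SOC level, where there are too few rows for a stable fit
  signals_soc <- with_stage("signals_soc", signal_stats(
    build_contingency(split$cohort, split$background, level = "SOC",
                      dictionary = dictionary),
    prior = attr(signals_pt, "gps_prior"),
    ic_method = config$ic_method, thresholds = config$thresholds
  ))

  tto <- with_stage("tto", {
    sample <- compute_tto(split$cohort)
    fit <- if (nrow(sample) >= 10 && length(unique(sample$days)) > 1) {
      fit_weibull(sample)
    } else NULL
    list(sample = sample,
         histogram = if (nrow(sample) > 0) monthly_histogram(sample) else NULL,
         fit = fit,
         curve = if (nrow(sample) > 0) cumulative_incidence(sample) else NULL,
         median_ci = if (nrow(sample) >= 2) median_ci_normal(sample) else NULL)
  })
  sex_comparison <- with_stage("sex_comparison", {
    nf <- sum(tto$sample$sex == "F", na.rm = TRUE)
    nm <- sum(tto$sample$sex == "M", na.rm = TRUE)
    if (nf >= 2 && nm >= 2) compare_tto_by_sex(tto$sample) else NULL
  })

  funnel <- tibble::tibble(
    stage = c("demo_rows_read", "after_deduplication", "linked_with_reaction",
              "target_cohort", "tto_evaluable"),
    n = c(n_raw, nrow(demo), nrow(reports), nrow(split$cohort),
          nrow(tto$sample))
  )

  report <- structure(
    list(funnel = funnel, baseline = baseline, signals_pt = signals_pt,
         signals_soc = signals_soc, tto = tto,
         sex_comparison = sex_comparison,
         manifest = tables$manifest %||% NULL, config = config),
    class = "pv_run_report"
  )
  if (!is.null(config$out_dir)) export_tables(report, config$out_dir)
  report
}

#' @export
print.pv_run_report <- function(x, ...) {
  cat("<pv_run_report>\n")
  print(x$funnel)
  cat("flagged signals:", sum(x$signals_pt$signal), "PT |",
      sum(x$signals_soc$signal), "SOC\n")
  if (!is.null(x$tto$fit)) {
    cat("Weibull shape", signif(x$tto$fit$shape, 3), "->",
        x$tto$fit$failure_class, "failure type\n")
  }
  invisible(x)
}

#' Export run-report tables to CSV and JSON
#'
#' Writes the baseline table, PT and SOC signal tables (all statistics,
#' interval bounds and the flag), the onset sample and its monthly
#' histogram, the cumulative-incidence curve, the sex comparison, and the
#' funnel as CSV files, plus a JSON mirror of the funnel, Weibull fit and
#' comparison. Ratio-scale statistics are exported at 3 decimals and
#' percents at 2, matching the printed conventions.
#'
#' @param report A `pv_run_report`.
#' @param dir Output directory (created if needed).
#' @param digits_ratio Decimals for ratio-scale statistics.
#' @return Named character vector of the files written, invisibly.
#' @export
export_tables <- function(report, dir, digits_ratio = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  wr <- function(tab, name) {
    path <- file.path(dir, name)
    readr::write_csv(tab, path, na = "")
    files[name] <<- path
  }
  wr(report$funnel, "funnel.csv")
  wr(report$baseline, "baseline.csv")
  round_sig <- function(tab) {
    dplyr::mutate(tab, dplyr::across(
      dplyr::any_of(c("ror", "ror_low", "ror_high", "prr", "chi2", "ic",
                      "ic025", "ebgm", "ebgm05", "E")),
      ~ round_half_up(.x, digits_ratio)
    ))
  }
  wr(round_sig(report$signals_pt), "signals_pt.csv")
  wr(round_sig(report$signals_soc), "signals_soc.csv")
  if (!is.null(report$tto$sample)) wr(report$tto$sample, "tto.csv")
  if (!is.null(report$tto$histogram)) wr(report$tto$histogram, "tto_monthly.csv")
  if (!is.null(report$tto$curve)) wr(report$tto$curve, "cumulative_incidence.csv")
  if (!is.null(report$sex_comparison)) wr(report$sex_comparison, "sex_comparison.csv")

  summary <- list(
    funnel = report$funnel,
    weibull = if (!is.null(report$tto$fit)) {
      f <- report$tto$fit
      list(shape = f$shape, shape_ci = f$shape_ci, scale = f$scale,
           scale_ci = f$scale_ci, failure_class = f$failure_class,
           median = f$median, median_ci = f$median_ci, n = f$n)
    },
    median_ci = report$tto$median_ci,
    sex_comparison = report$sex_comparison,
    n_signals_pt = sum(report$signals_pt$signal),
    n_signals_soc = sum(report$signals_soc$signal)
  )
  path <- file.path(dir, "run_report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  files["run_report.json"] <- path
  invisible(files)
}
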