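# End-to-end orchestration: clean -> detect -> screen -> subgroup -> onset,
# with a descriptive summary, CSV outputs and a run manifest.

#' Descriptive summary of a cleaned dataset
#'
#' Counts and percentages (over total reports) by sex, weight band, age
#' band, reporter code, serious outcome and top reporting countries. A
#' report with several outcome codes contributes to each code's row, so
#' outcome percentages need not sum to 100.
#'
#' @param dataset A `pv_dataset`.
#' @param target_only Summarise target-drug reports only (default `TRUE`).
#' @param top_countries Number of countries to list.
#' @return Tibble with `category`, `level`, `n`, `pct`.
#' @export
describe_dataset <- function(dataset, target_only = TRUE,
                             top_countries = 5) {
  stopifnot(inherits(dataset, "pv_dataset"))
  rep <- dataset$reports
  if (target_only) rep <- dplyr::filter(rep, .data$target)
  n_tot <- nrow(rep)
  row <- function(category, level, n) {
    tibble::tibble(category = category, level = level, n = n,
                   pct = if (n_tot > 0) 100 * n / n_tot else NA_real_)
  }
  lvl_count <- function(category, x, levels) {
    purrr::map_dfr(levels, function(l) row(category, l, sum(x == l)))
  }
  sex_tbl <- lvl_count("sex", rep$sex, c("F", "M", "UNKNOWN"))
  wt_band <- dplyr::case_when(
    is.na(rep$weight_kg) ~ "unknown",
    rep$weight_kg < 50 ~ "<50",
    rep$weight_kg <= 100 ~ "50-100",
    TRUE ~ ">100")
  wt_tbl <- lvl_count("weight_kg", wt_band,
                      c("<50", "50-100", ">100", "unknown"))
  age_band <- dplyr::case_when(
    is.na(rep$age_years) ~ "unknown",
    rep$age_years < 18 ~ "<18",
    rep$age_years < 65 ~ "18-64.9",
    rep$age_years <= 85 ~ "65-85",
    TRUE ~ ">85")
  age_tbl <- lvl_count("age_years", age_band,
                       c("<18", "18-64.9", "65-85", ">85", "unknown"))
  reporter_tbl <- lvl_count("reporter", rep$reporter_code,
                            c("CN", "HP", "MD", "OT", "PH", "UNKNOWN"))
  outc <- dataset$outcomes |>
    dplyr::filter(.data$primaryid %in% rep$primaryid)
  outc_tbl <- purrr::map_dfr(c("DE", "HO", "DS", "CA", "LT", "RI", "OT"),
                             function(code) {
                               row("outcome", code,
                                   sum(outc$outc_cod == code))
                             })
  no_outc <- sum(!(rep$primaryid %in% outc$primaryid))
  outc_tbl <- dplyr::bind_rows(outc_tbl, row("outcome", "NONE", no_outc))
  country_counts <- rep |>
    dplyr::filter(nzchar(.data$country)) |>
    dplyr::count(.data$country, sort = TRUE) |>
    dplyr::slice_head(n = top_countries)
  country_tbl <- purrr::map2_dfr(country_counts$country, country_counts$n,
                                 function(l, n) row("country", l, n))
  year_tbl <- rep |>
    dplyr::mutate(year = substr(.data$fda_dt, 1, 4)) |>
    dplyr::count(.data$year) |>
    dplyr::arrange(.data$year) |>
    dplyr::transmute(category = "reporting_year", level = .data$year,
                     n = .data$n, pct = 100 * .data$n / n_tot)
  dplyr::bind_rows(
    row("total", "reports", n_tot),
    sex_tbl, wt_tbl, age_tbl, reporter_tbl, outc_tbl, country_tbl, year_tbl)
}

#' Run the full signal-detection pipeline
#'
#' Cleans (or generates) the data, computes per-PT disproportionality with
#' the four-algorithm combined call, aggregates at SOC and narrow-SMQ
#' level, screens combined positives against the DME list, runs sex- and
#' age-stratified subgroup analyses on the positives, summarises and fits
#' time-to-onset, and (optionally) writes the CSV bundle plus a
#' `manifest.json`. Identical input and configuration give byte-identical
#' outputs.
#'
#' @param input Either a [synthetic_config()], a `pv_synth_tables`, a
#'   `pv_raw_quarter`, or a directory path readable by [read_quarter()].
#' @param maps Term maps from [load_term_maps()].
#' @param synonyms Target-drug synonym vector.
#' @param hyper,dialect Passed to [signal_metrics()].
#' @param m_tests Optional Bonferroni override.
#' @param out_dir Directory for the CSV bundle; `NULL` (default) skips
#'   writing.
#' @return List of class `pv_run`: `dataset`, `descriptive`, `signals`,
#'   `soc_signals`, `smq_summary`, `volcano`, `dme_screen`, `sex_signals`,
#'   `age_or`, `tto`, `tto_summary`, `weibull_fit` (or `NULL` when too few
#'   onsets), `manifest`.
#' @export
pv_run <- function(input, maps = load_term_maps(),
                   synonyms = load_synonyms(),
                   hyper = bcpnn_hyperparams(), dialect = "corrected",
                   m_tests = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  raw <- stage("input", {
    if (inherits(input, "pv_synth_config")) {
      generate_tables(input)
    } else if (inherits(input, c("pv_synth_tables", "pv_raw_quarter"))) {
      input
    } else if (is.character(input) && length(input) == 1) {
      read_quarter(input)
    } else {
      stop("unrecognised input type")
    }
  })
  ground_truth <- if (inherits(raw, "pv_synth_tables")) raw$ground_truth
  dataset <- stage("assemble", assemble_dataset(raw, synonyms))
  descriptive <- stage("describe", describe_dataset(dataset))

  counts <- stage("contingency", pt_contingency(dataset))
  signals <- stage("signals",
                   signal_metrics(counts, hyper = hyper, dialect = dialect,
                                  m_tests = m_tests))
  positives <- signals$pt[signals$combined_pos]
  soc_signals <- stage("soc", aggregate_by_group(dataset, maps, "soc",
                                                 hyper = hyper,
                                                 dialect = dialect))
  smq_summary <- stage("smq", {
    if (length(positives)) {
      aggregate_by_group(dataset, maps, "smq", positive_pts = positives,
                         hyper = hyper, dialect = dialect)
    } else {
      tibble::tibble()
    }
  })
  volcano <- stage("volcano", volcano_table(signals))
  dme <- stage("dme_screen", screen_dme(signals, maps))
  sex_tbl <- stage("sex_ror", {
    if (length(positives)) sex_ror(dataset, positives) else tibble::tibble()
  })
  age_tbl <- stage("logistic_or", {
    if (length(positives)) logistic_or(dataset, positives)
    else tibble::tibble()
  })
  tto <- stage("tto", extract_tto(dataset, synonyms))
  tto_ok <- tto$days[tto$reason == "ok"]
  tto_sum <- stage("tto_summary", summarize_tto(tto_ok))
  wb <- stage("weibull", {
    if (length(tto_ok) >= 3 && length(unique(tto_ok)) > 1) {
      fit_weibull(tto_ok)
    }
  })

  manifest <- list(
    package = "pvkit",
    n_demo_rows_raw = dataset$counts$n_demo_rows_raw,
    n_reac_rows_raw = dataset$counts$n_reac_rows_raw,
    deleted_removed = dataset$counts$deleted_removed,
    dedup_removed = dataset$counts$dedup_removed,
    n_reports = dataset$counts$n_reports,
    n_target_reports = dataset$counts$n_target_reports,
    n_event_records = dataset$counts$n_event_records,
    n_target_event_records = dataset$counts$n_target_event_records,
    orphan_events_dropped = dataset$counts$orphan_events_dropped,
    m_tests = attr(signals, "m_tests"),
    n_pts_tested = nrow(signals),
    n_combined_positive = length(positives),
    n_socs = sum(soc_signals$group != "UNMAPPED"),
    tto_exclusions = as.list(table(tto$reason)),
    n_tto = length(tto_ok))

  out <- structure(list(
    dataset = dataset, descriptive = descriptive, signals = signals,
    soc_signals = soc_signals, smq_summary = smq_summary, volcano = volcano,
    dme_screen = dme, sex_signals = sex_tbl, age_or = age_tbl,
    tto = tto, tto_summary = tto_sum, weibull_fit = wb,
    ground_truth = ground_truth, manifest = manifest),
    class = "pv_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write the CSV bundle of a pipeline run
#'
#' @param run A `pv_run`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "pv_run"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(tbl), path)
    path
  }
  paths <- c(
    descriptive = w(run$descriptive, "descriptive_summary.csv"),
    signals = w(run$signals, "signals.csv"),
    soc = w(run$soc_signals, "soc_signals.csv"),
    smq = w(run$smq_summary, "smq_summary.csv"),
    volcano = w(run$volcano, "volcano.csv"),
    dme = w(run$dme_screen, "dme_screen.csv"),
    sex = w(run$sex_signals, "sex_signals.csv"),
    age = w(run$age_or, "age_or.csv"),
    tto = w(run$tto, "tto_records.csv"),
    tto_summary = w(run$tto_summary, "tto_summary.csv"),
    tto_bins = w(tto_bins(run$tto_summary), "tto_bins.csv"))
  if (!is.null(run$weibull_fit)) {
    paths <- c(paths, weibull = w(tidy(run$weibull_fit), "weibull_fit.csv"))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = manifest_path))
}

#' @export
print.pv_run <- function(x, ...) {
  m <- x$manifest
  cat("<pv_run>\n")
  cat(sprintf("  %d reports (%d target), %d event records\n",
              m$n_reports, m$n_target_reports, m$n_event_records))
  cat(sprintf("  %d PTs tested, %d combined positives, %d SOCs\n",
              m$n_pts_tested, m$n_combined_positive, m$n_socs))
  cat(sprintf("  %d onset delays analysed\n", m$n_tto))
  invisible(x)
}
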