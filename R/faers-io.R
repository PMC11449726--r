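# Reading FAERS-dialect quarterly ASCII tables, case deduplication,
# primary-suspect target-drug selection, and assembly of the analysis set.

.mandatory_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "outc_cod"))

#' Read a FAERS-dialect quarter from disk
#'
#' Reads the `$`-delimited DEMO/DRUG/REAC/THER/OUTC files plus the
#' deleted-case list. All columns are read as character; dates stay in the
#' raw CCYYMMDD form (partial dates are kept as-is and only classified at
#' use). Row counts are preserved exactly.
#'
#' @param dir Directory containing `DEMOyyQq.txt` etc. and, optionally,
#'   `deleted_cases.txt`. Alternatively pass `paths`.
#' @param paths Optional named character vector (`demo`, `drug`, `reac`,
#'   `ther`, `outc`, and optionally `deleted`) overriding `dir` discovery.
#' @return List of class `pv_raw_quarter` with tibbles `demo`, `drug`,
#'   `reac`, `ther`, `outc` and character vector `deleted`.
#' @export
read_quarter <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(dir.exists(dir))
    find1 <- function(prefix) {
      hit <- list.files(dir, pattern = paste0("^", prefix, ".*\\.txt$"),
                        full.names = TRUE)
      if (length(hit) != 1) {
        stop("expected exactly one ", prefix, "*.txt in ", dir, call. = FALSE)
      }
      hit
    }
    paths <- c(demo = find1("DEMO"), drug = find1("DRUG"),
               reac = find1("REAC"), ther = find1("THER"),
               outc = find1("OUTC"))
    del <- file.path(dir, "deleted_cases.txt")
    if (file.exists(del)) paths <- c(paths, deleted = del)
  }
  read1 <- function(name) {
    tbl <- readr::read_delim(paths[[name]], delim = "$",
                             col_types = readr::cols(.default = "c"),
                             na = character(), progress = FALSE)
    miss <- setdiff(.mandatory_cols[[name]], names(tbl))
    if (length(miss)) {
      stop(sprintf("%s table is missing mandatory column(s): %s",
                   toupper(name), paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    tbl
  }
  out <- lapply(c(demo = "demo", drug = "drug", reac = "reac",
                  ther = "ther", outc = "outc"), read1)
  out$deleted <- if ("deleted" %in% names(paths)) {
    del <- readLines(paths[["deleted"]])
    del[nzchar(trimws(del))]
  } else {
    character(0)
  }
  structure(out, class = "pv_raw_quarter")
}

# Coerce generated in-memory tables to the all-character form read_quarter
# would return, so both entry points share one assembly path.
.as_raw_quarter <- function(tables) {
  chr <- function(tbl) dplyr::mutate(tbl, dplyr::across(
    dplyr::everything(), ~ dplyr::coalesce(as.character(.x), "")))
  structure(list(demo = chr(tables$demo), drug = chr(tables$drug),
                 reac = chr(tables$reac), ther = chr(tables$ther),
                 outc = chr(tables$outc),
                 deleted = tables$deleted %||% character(0)),
            class = "pv_raw_quarter")
}

#' Deduplicate FAERS case versions
#'
#' One spontaneous case (CASEID) can appear as several report versions
#' (PRIMARYIDs). For each CASEID the version with the latest FDA receipt
#' date is kept; when receipt dates tie, the highest PRIMARYID wins.
#' Cases on the deleted list are removed entirely. The operation is
#' idempotent and independent of the input row order.
#'
#' @param demo Data frame with at least `caseid`, `primaryid`, `fda_dt`.
#' @param deleted_caseids Character vector of CASEIDs to drop.
#' @return Tibble with exactly one row per surviving CASEID.
#' @export
deduplicate_cases <- function(demo, deleted_caseids = character(0)) {
  stopifnot(all(c("caseid", "primaryid", "fda_dt") %in% names(demo)))
  demo |>
    tibble::as_tibble() |>
    dplyr::filter(!(.data$caseid %in% as.character(deleted_caseids))) |>
    dplyr::mutate(.fda = suppressWarnings(as.numeric(.data$fda_dt)),
                  .pid = suppressWarnings(as.numeric(.data$primaryid))) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$.fda),
                   dplyr::desc(.data$.pid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-".fda", -".pid")
}

#' Load a drug synonym dictionary
#'
#' One synonym per line; blank lines and `#` comments ignored. Names are
#' normalised with [normalize_drug_name()].
#'
#' @param path File path. Defaults to the bundled eslicarbazepine set.
#' @return Character vector of normalised synonyms.
#' @export
load_synonyms <- function(path = system.file("extdata",
                                             "esl_synonyms.txt",
                                             package = "pvkit")) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(normalize_drug_name(x[nzchar(x)]))
  if (!length(x)) stop("synonym dictionary is empty", call. = FALSE)
  x
}

#' Test drug names against a synonym dictionary
#'
#' Case-insensitive, whitespace/punctuation-normalised membership test.
#'
#' @param drugname Character vector of verbatim drug names.
#' @param synonyms Character vector of synonyms (normalised internally).
#' @return Logical vector.
#' @export
match_target_drug <- function(drugname, synonyms) {
  if (length(synonyms) == 0) {
    stop("synonym dictionary is empty", call. = FALSE)
  }
  normalize_drug_name(drugname) %in% normalize_drug_name(synonyms)
}

# FAERS age-unit conversion to years; out-of-range ages set missing.
.age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  factor_tbl <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_tbl[cod])
  f[is.na(f) & !is.na(age)] <- 1  # blank unit treated as years
  yrs <- age * f
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

#' Assemble the cleaned analysis dataset
#'
#' Applies deduplication and deleted-case removal, normalises demographics
#' (sex to F/M/UNKNOWN, age to years, implausible ages dropped), flags
#' reports whose primary-suspect drug matches the target synonym list,
#' collapses duplicate (report, PT) event rows, and drops orphan rows whose
#' PRIMARYID has no surviving report (counted in the attributes).
#'
#' @param raw A `pv_raw_quarter` from [read_quarter()], or a
#'   `pv_synth_tables` from [generate_tables()].
#' @param synonyms Target-drug synonym vector, see [load_synonyms()].
#' @return List of class `pv_dataset`: tibbles `reports` (one row per
#'   surviving case, with `target` flag), `events` (distinct report-PT
#'   pairs), `drugs`, `ther`, `outcomes`, plus a `counts` list
#'   (`n_reports`, `n_target_reports`, `n_event_records`,
#'   `n_target_event_records`, `dedup_removed`, `deleted_removed`,
#'   `orphan_events_dropped`).
#' @export
assemble_dataset <- function(raw, synonyms = load_synonyms()) {
  if (inherits(raw, "pv_synth_tables")) raw <- .as_raw_quarter(raw)
  stopifnot(inherits(raw, "pv_raw_quarter"))

  n_demo_raw <- nrow(raw$demo)
  n_deleted_rows <- sum(raw$demo$caseid %in% raw$deleted)
  demo <- deduplicate_cases(raw$demo, raw$deleted)
  dedup_removed <- n_demo_raw - n_deleted_rows - nrow(demo)

  keep_pid <- demo$primaryid
  drugs <- raw$drug |>
    dplyr::filter(.data$primaryid %in% keep_pid) |>
    dplyr::mutate(drug_seq = as.integer(.data$drug_seq),
                  role_cod = toupper(trimws(.data$role_cod)))
  ther <- raw$ther |>
    dplyr::filter(.data$primaryid %in% keep_pid) |>
    dplyr::mutate(dsg_drug_seq = as.integer(.data$dsg_drug_seq))
  outcomes <- raw$outc |>
    dplyr::filter(.data$primaryid %in% keep_pid) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod)

  n_reac_raw <- nrow(raw$reac)
  events <- raw$reac |>
    dplyr::mutate(pt = normalize_pt(.data$pt)) |>
    dplyr::filter(nzchar(.data$pt))
  orphan <- sum(!(events$primaryid %in% keep_pid))
  events <- events |>
    dplyr::filter(.data$primaryid %in% keep_pid) |>
    dplyr::distinct(.data$primaryid, .data$pt)

  target_pids <- drugs |>
    dplyr::filter(.data$role_cod == "PS",
                  match_target_drug(.data$drugname, synonyms)) |>
    dplyr::pull("primaryid") |>
    unique()

  sex_raw <- toupper(trimws(demo$sex %||% rep("", nrow(demo))))
  reports <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt %||% rep("", nrow(demo)),
    sex = dplyr::if_else(sex_raw %in% c("F", "M"), sex_raw, "UNKNOWN"),
    age_years = .age_to_years(demo$age %||% rep(NA, nrow(demo)),
                              demo$age_cod %||% rep("", nrow(demo))),
    weight_kg = {
      w <- suppressWarnings(as.numeric(demo$wt %||% rep(NA, nrow(demo))))
      w[!is.na(w) & w <= 0] <- NA_real_
      w
    },
    reporter_code = {
      r <- toupper(trimws(demo$occp_cod %||% rep("", nrow(demo))))
      dplyr::if_else(r %in% c("CN", "HP", "MD", "OT", "PH"), r, "UNKNOWN")
    },
    country = trimws(demo$reporter_country %||% rep("", nrow(demo))),
    target = .data$primaryid %in% target_pids)

  target_events <- events$primaryid %in% reports$primaryid[reports$target]
  structure(list(
    reports = reports, events = events, drugs = drugs, ther = ther,
    outcomes = outcomes,
    counts = list(
      n_demo_rows_raw = n_demo_raw,
      n_reac_rows_raw = n_reac_raw,
      n_reports = nrow(reports),
      n_target_reports = sum(reports$target),
      n_event_records = nrow(events),
      n_target_event_records = sum(target_events),
      dedup_removed = dedup_removed,
      deleted_removed = n_deleted_rows,
      orphan_events_dropped = orphan)),
    class = "pv_dataset")
}

#' @export
print.pv_dataset <- function(x, ...) {
  cat("<pv_dataset>\n")
  cat(sprintf("  reports: %d (%d target-drug PS)\n",
              x$counts$n_reports, x$counts$n_target_reports))
  cat(sprintf("  event records: %d (%d on target reports)\n",
              x$counts$n_event_records, x$counts$n_target_event_records))
  cat(sprintf("  removed: %d duplicate version(s), %d deleted case row(s)\n",
              x$counts$dedup_removed, x$counts$deleted_removed))
  invisible(x)
}

#' Time-to-onset from a pair of CCYYMMDD date strings
#'
#' Day difference event minus start. Pairs with a partial (4/6-digit),
#' missing or invalid date, or a non-positive difference, are excluded with
#' a reason code rather than returned.
#'
#' @param start_dt,event_dt Character vectors of CCYYMMDD strings.
#' @return Tibble with `days` (integer, `NA` when excluded) and `reason`
#'   (`"ok"`, `"missing_date"`, `"partial_date"`, `"invalid_date"`,
#'   `"nonpositive"`).
#' @export
tto_days <- function(start_dt, event_dt) {
  cls_s <- classify_faers_date(start_dt)
  cls_e <- classify_faers_date(event_dt)
  reason <- rep("ok", length(cls_s))
  reason[cls_s == "invalid" | cls_e == "invalid"] <- "invalid_date"
  reason[cls_s == "partial" | cls_e == "partial"] <- "partial_date"
  reason[cls_s == "missing" | cls_e == "missing"] <- "missing_date"
  days <- rep(NA_integer_, length(cls_s))
  ok <- reason == "ok"
  if (any(ok)) {
    d <- as.integer(parse_faers_date(event_dt[ok]) -
                      parse_faers_date(start_dt[ok]))
    days[ok] <- d
  }
  nonpos <- ok & !is.na(days) & days <= 0
  reason[nonpos] <- "nonpositive"
  days[reason != "ok"] <- NA_integer_
  tibble::tibble(days = days, reason = reason)
}

#' Extract time-to-onset samples for the target drug
#'
#' For each target-drug report, the earliest complete therapy start date of
#' the primary-suspect target drug is paired with the report's event onset
#' date, and [tto_days()] exclusion rules applied.
#'
#' @param dataset A `pv_dataset`.
#' @param synonyms Target-drug synonym vector.
#' @return Tibble with `primaryid`, `days`, `reason`; rows with
#'   `reason == "ok"` carry positive integer days.
#' @export
extract_tto <- function(dataset, synonyms = load_synonyms()) {
  stopifnot(inherits(dataset, "pv_dataset"))
  target_reports <- dplyr::filter(dataset$reports, .data$target)
  ps_target <- dataset$drugs |>
    dplyr::filter(.data$role_cod == "PS",
                  match_target_drug(.data$drugname, synonyms),
                  .data$primaryid %in% target_reports$primaryid)
  starts <- ps_target |>
    dplyr::select("primaryid", "drug_seq") |>
    dplyr::inner_join(dataset$ther,
                      by = c("primaryid", "drug_seq" = "dsg_drug_seq")) |>
    dplyr::mutate(complete = classify_faers_date(.data$start_dt) ==
                    "complete") |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_dt = if (any(.data$complete)) {
      sd <- .data$start_dt[.data$complete]
      sd[which.min(as.numeric(sd))]
    } else {
      .data$start_dt[1]
    }, .groups = "drop")
  joined <- target_reports |>
    dplyr::left_join(starts, by = "primaryid") |>
    dplyr::mutate(start_dt = dplyr::coalesce(.data$start_dt, ""))
  res <- tto_days(joined$start_dt, joined$event_dt)
  tibble::tibble(primaryid = joined$primaryid, days = res$days,
                 reason = res$reason)
}
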