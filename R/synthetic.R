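# Synthetic spontaneous-report generator.
#
# Emulates the FAERS quarterly ASCII layout (DEMO/DRUG/REAC/THER/OUTC plus a
# deleted-case list) with known ground truth: planted drug-event associations
# of specified report-level odds ratio, duplicate case versions exercising
# both deduplication branches, heavy demographic missingness, partial dates,
# and Weibull-distributed onset delays. Every probability the generator uses
# is recorded so downstream estimates can be checked against truth.

#' Default preferred-term vocabulary for the synthetic generator
#'
#' Named numeric vector of background per-report occurrence probabilities.
#' The roster mixes the common tolerability events of a sodium-channel
#' blocker anticonvulsant with the rare serious events a signal-detection
#' run should surface; rare planted-capable terms sit at 0.003.
#'
#' @return Named numeric vector (names are PTs, values probabilities).
#' @export
default_pt_vocabulary <- function() {
  c(
    "DRUG INEFFECTIVE" = 0.200,
    "SEIZURE" = 0.120,
    "DIZZINESS" = 0.100,
    "HEADACHE" = 0.090,
    "NAUSEA" = 0.070,
    "SOMNOLENCE" = 0.060,
    "FATIGUE" = 0.060,
    "FALL" = 0.050,
    "VOMITING" = 0.040,
    "INSOMNIA" = 0.040,
    "WEIGHT DECREASED" = 0.030,
    "RASH" = 0.030,
    "DIPLOPIA" = 0.020,
    "AMNESIA" = 0.020,
    "CONFUSIONAL STATE" = 0.015,
    "AGGRESSION" = 0.010,
    "AGITATION" = 0.010,
    "IRRITABILITY" = 0.010,
    "SUICIDAL IDEATION" = 0.010,
    "ABNORMAL BEHAVIOUR" = 0.008,
    "OVERDOSE" = 0.020,
    "HYPONATRAEMIA" = 0.003,
    "BALANCE DISORDER" = 0.003,
    "MEMORY IMPAIRMENT" = 0.003,
    "RASH MACULO-PAPULAR" = 0.004,
    "DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS" = 0.003,
    "STEVENS-JOHNSON SYNDROME" = 0.003,
    "TOXIC SKIN ERUPTION" = 0.002,
    "DERMATITIS EXFOLIATIVE" = 0.002
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Assembles and validates the full parameter set of the generator. Defaults
#' describe the study conditions the package's calibration tests run under:
#' about a tenth of reports name the target drug as primary suspect, age is
#' missing on ~65% of reports and weight on ~87% (typical consumer-reported
#' spontaneous data), onset delays follow a Weibull with shape 0.69 and scale
#' 53.29 days (an early-failure profile), and three associations of known
#' report-level odds ratio are planted for the target drug.
#'
#' @param n_cases Number of distinct cases (CASEIDs) to generate.
#' @param target_share Probability a case's primary-suspect drug is the
#'   target drug.
#' @param duplicate_rate Fraction of cases receiving a second report version
#'   (half with a later receipt date and a lower PRIMARYID, half with an
#'   equal receipt date and a higher PRIMARYID, so both deduplication
#'   branches are exercised).
#' @param deleted_rate Fraction of cases flagged on the deleted-case list.
#' @param target_drug Canonical target drug name.
#' @param target_aliases Character vector of alternative spellings/trade
#'   names the generator writes into DRUG rows for target reports.
#' @param background_drugs Character vector of comparator drug names.
#' @param pt_vocabulary Named numeric vector of background PT probabilities
#'   in (0, 1); see [default_pt_vocabulary()].
#' @param planted_signals Named numeric vector: PT -> true report-level
#'   odds ratio (vs the background probability) for target-drug reports.
#' @param sex_effects Named numeric vector: PT -> male-vs-female odds ratio
#'   applied within target-drug reports (female kept at baseline).
#' @param age_effects Data frame with columns `pt`, `group`
#'   (`"children"`/`"elderly"`), `or`: odds ratio vs the adult baseline,
#'   applied within target-drug reports.
#' @param sex_probs Named probabilities for true sex, names `F`, `M`.
#' @param age_group_probs Named probabilities for `children`, `adult`,
#'   `elderly` true age group.
#' @param missing_sex_rate,missing_age_rate,missing_weight_rate Fractions of
#'   reports whose sex/age/weight fields are blanked.
#' @param date_error_rate Fraction of reports whose therapy start or event
#'   date is corrupted to a partial (6-digit) date.
#' @param dup_pt_rate Fraction of event rows duplicated verbatim in REAC.
#' @param tto_shape,tto_scale Weibull shape/scale (days) of true onset delay.
#' @param quarter Quarter tag used in generated file names, e.g. `"24Q1"`.
#' @param seed Integer seed; identical configurations generate identical
#'   tables.
#' @return A list of class `pv_synth_config`.
#' @export
synthetic_config <- function(n_cases = 20000,
                             target_share = 0.1,
                             duplicate_rate = 0.1,
                             deleted_rate = 0.02,
                             target_drug = "ESLICARBAZEPINE ACETATE",
                             target_aliases = c("ESLICARBAZEPINE ACETATE",
                                                "Aptiom", "ZEBINIX",
                                                "eslicarbazepine", "Exalief"),
                             background_drugs = c("CARBAMAZEPINE",
                                                  "OXCARBAZEPINE",
                                                  "LEVETIRACETAM",
                                                  "LAMOTRIGINE",
                                                  "VALPROIC ACID",
                                                  "TOPIRAMATE",
                                                  "PHENYTOIN",
                                                  "LACOSAMIDE"),
                             pt_vocabulary = default_pt_vocabulary(),
                             planted_signals = c("HYPONATRAEMIA" = 10,
                                                 "BALANCE DISORDER" = 5,
                                                 "MEMORY IMPAIRMENT" = 2),
                             sex_effects = c("SEIZURE" = 1.64),
                             age_effects = data.frame(
                               pt = c("AGGRESSION", "CONFUSIONAL STATE"),
                               group = c("children", "elderly"),
                               or = c(3, 2)),
                             sex_probs = c("F" = 0.6, "M" = 0.4),
                             age_group_probs = c(children = 0.114,
                                                 adult = 0.714,
                                                 elderly = 0.172),
                             missing_sex_rate = 0.295,
                             missing_age_rate = 0.655,
                             missing_weight_rate = 0.87,
                             date_error_rate = 0.05,
                             dup_pt_rate = 0.02,
                             tto_shape = 0.69,
                             tto_scale = 53.29,
                             quarter = "24Q1",
                             seed = 1L) {
  stopifnot(length(n_cases) == 1, n_cases >= 0, n_cases == floor(n_cases))
  stop_if_not_prob(target_share, "target_share")
  stop_if_not_prob(duplicate_rate, "duplicate_rate")
  stop_if_not_prob(deleted_rate, "deleted_rate")
  stop_if_not_prob(missing_sex_rate, "missing_sex_rate")
  stop_if_not_prob(missing_age_rate, "missing_age_rate")
  stop_if_not_prob(missing_weight_rate, "missing_weight_rate")
  stop_if_not_prob(date_error_rate, "date_error_rate")
  stop_if_not_prob(dup_pt_rate, "dup_pt_rate")
  if (duplicate_rate >= 1 || deleted_rate >= 1) {
    stop("`duplicate_rate` and `deleted_rate` must be < 1", call. = FALSE)
  }
  if (length(pt_vocabulary) == 0) {
    stop("`pt_vocabulary` must not be empty", call. = FALSE)
  }
  if (any(pt_vocabulary <= 0 | pt_vocabulary >= 1)) {
    stop("`pt_vocabulary` probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (length(c(target_drug, background_drugs)) == 0) {
    stop("at least one drug is required", call. = FALSE)
  }
  planted_signals <- planted_signals %||% numeric(0)
  if (length(planted_signals)) {
    if (any(planted_signals <= 0)) {
      stop("planted odds ratios must be strictly positive", call. = FALSE)
    }
    missing_pt <- setdiff(names(planted_signals), names(pt_vocabulary))
    if (length(missing_pt)) {
      stop("planted PTs not in vocabulary: ",
           paste(missing_pt, collapse = ", "), call. = FALSE)
    }
  }
  sex_effects <- sex_effects %||% numeric(0)
  age_effects <- age_effects %||%
    data.frame(pt = character(), group = character(), or = numeric())
  stopifnot(all(age_effects$group %in% c("children", "elderly")),
            all(age_effects$or > 0), all(sex_effects > 0))
  sex_probs <- sex_probs / sum(sex_probs)
  age_group_probs <- age_group_probs / sum(age_group_probs)
  stopifnot(tto_shape > 0, tto_scale > 0)
  structure(
    list(n_cases = as.integer(n_cases), target_share = target_share,
         duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
         target_drug = target_drug, target_aliases = target_aliases,
         background_drugs = background_drugs, pt_vocabulary = pt_vocabulary,
         planted_signals = planted_signals, sex_effects = sex_effects,
         age_effects = age_effects, sex_probs = sex_probs,
         age_group_probs = age_group_probs,
         missing_sex_rate = missing_sex_rate,
         missing_age_rate = missing_age_rate,
         missing_weight_rate = missing_weight_rate,
         date_error_rate = date_error_rate, dup_pt_rate = dup_pt_rate,
         tto_shape = tto_shape, tto_scale = tto_scale,
         quarter = quarter, seed = as.integer(seed)),
    class = "pv_synth_config")
}

#' Invert an odds ratio into the exposed-arm event probability
#'
#' Given a true odds ratio and the comparator-arm probability, returns the
#' exposed-arm probability whose odds are `true_or` times the comparator
#' odds. This is how the generator plants associations: adjusting
#' P(PT | drug) at the report level, never editing counts.
#'
#' @param true_ror True odds ratio (> 0).
#' @param p_other Comparator-arm event probability in (0, 1).
#' @return Named list with `p_target` and `p_other`;
#'   `odds(p_target)/odds(p_other) == true_ror` to machine precision.
#' @examples
#' derive_event_probs(4, 0.5)$p_target  # 0.8
#' @export
derive_event_probs <- function(true_ror, p_other) {
  if (!is.finite(true_ror) || true_ror <= 0) {
    stop("`true_ror` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(p_other) || p_other <= 0 || p_other >= 1) {
    stop("`p_other` must lie strictly inside (0, 1)", call. = FALSE)
  }
  o <- true_ror * odds_of(p_other)
  if (!is.finite(o)) stop("implied odds are not finite", call. = FALSE)
  list(p_target = inv_odds(o), p_other = p_other)
}

# Date helpers on integer days since epoch, formatted CCYYMMDD.
.rand_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + floor(runif(n) * (as.numeric(to - from) + 1))
}

#' Generate synthetic FAERS-style quarterly tables
#'
#' Produces DEMO/DRUG/REAC/THER/OUTC tables in the FAERS quarterly ASCII
#' column layout, a deleted-case list, and a ground-truth record of every
#' probability used. Planted associations, sex effects and age effects act
#' on the report-level event probabilities of target-drug reports, so the
#' full cleaning/dedup/counting path is exercised when they are recovered.
#'
#' @param config A [synthetic_config()].
#' @return List of class `pv_synth_tables` with elements `demo`, `drug`,
#'   `reac`, `ther`, `outc` (tibbles), `deleted` (character CASEIDs),
#'   `ground_truth` (list) and `quarter`.
#' @export
generate_tables <- function(config) {
  stopifnot(inherits(config, "pv_synth_config"))
  withr::with_seed(config$seed, .generate_tables_impl(config))
}

.generate_tables_impl <- function(cfg) {
  n <- cfg$n_cases
  pts <- names(cfg$pt_vocabulary)
  J <- length(pts)

  if (n == 0) {
    empty <- .empty_tables()
    empty$ground_truth <- list(
      planted = tibble::tibble(pt = character(), true_ror = numeric(),
                               p_target = numeric(), p_other = numeric()),
      surviving = tibble::tibble(caseid = character(), primaryid = character()),
      deleted_caseids = character(0),
      n_cases = 0L, n_surviving = 0L, n_surviving_target = 0L,
      tto_shape = cfg$tto_shape, tto_scale = cfg$tto_scale)
    empty$quarter <- cfg$quarter
    return(empty)
  }

  caseid <- sprintf("%d", 1000000L + seq_len(n))
  is_target <- runif(n) < cfg$target_share
  drug <- ifelse(is_target, cfg$target_drug,
                 sample(cfg$background_drugs, n, replace = TRUE))

  sex_true <- sample(names(cfg$sex_probs), n, replace = TRUE,
                     prob = cfg$sex_probs)
  age_group_true <- sample(names(cfg$age_group_probs), n, replace = TRUE,
                           prob = cfg$age_group_probs)
  age_true <- numeric(n)
  age_true[age_group_true == "children"] <-
    runif(sum(age_group_true == "children"), 1, 17.9)
  age_true[age_group_true == "adult"] <-
    runif(sum(age_group_true == "adult"), 18, 64.9)
  age_true[age_group_true == "elderly"] <-
    runif(sum(age_group_true == "elderly"), 65, 90)

  # Per-report, per-PT Bernoulli probabilities: background everywhere,
  # odds-shifted for planted / sex / age effects on target-drug reports.
  P <- matrix(rep(cfg$pt_vocabulary, each = n), nrow = n,
              dimnames = list(NULL, pts))
  planted_truth <- tibble::tibble(pt = character(), true_ror = numeric(),
                                  p_target = numeric(), p_other = numeric())
  for (pt in names(cfg$planted_signals)) {
    pr <- derive_event_probs(cfg$planted_signals[[pt]], cfg$pt_vocabulary[[pt]])
    P[is_target, pt] <- pr$p_target
    planted_truth <- dplyr::bind_rows(planted_truth, tibble::tibble(
      pt = pt, true_ror = unname(cfg$planted_signals[[pt]]),
      p_target = pr$p_target, p_other = pr$p_other))
  }
  for (pt in names(cfg$sex_effects)) {
    idx <- is_target & sex_true == "M"
    P[idx, pt] <- shift_odds(P[idx, pt], cfg$sex_effects[[pt]])
  }
  if (nrow(cfg$age_effects)) {
    for (k in seq_len(nrow(cfg$age_effects))) {
      eff <- cfg$age_effects[k, ]
      idx <- is_target & age_group_true == eff$group
      P[idx, eff$pt] <- shift_odds(P[idx, eff$pt], eff$or)
    }
  }

  draws <- matrix(runif(n * J), n, J) < P
  # every report must list at least one PT: redraw empty rows
  for (i in 1:100) {
    empty_rows <- which(rowSums(draws) == 0L)
    if (!length(empty_rows)) break
    draws[empty_rows, ] <-
      matrix(runif(length(empty_rows) * J), length(empty_rows), J) <
      P[empty_rows, , drop = FALSE]
  }
  empty_rows <- which(rowSums(draws) == 0L)
  if (length(empty_rows)) draws[empty_rows, which.max(cfg$pt_vocabulary)] <- TRUE

  # demographics as reported (missingness applied after effects used truth)
  sex_rep <- sex_true
  sex_rep[runif(n) < cfg$missing_sex_rate] <- "UNK"
  age_rep <- round(age_true, 1)
  age_cod <- rep("YR", n)
  # a slice of child ages arrives in months, exercising unit conversion
  mon <- age_group_true == "children" & runif(n) < 0.3
  age_rep[mon] <- round(age_true[mon] * 12)
  age_cod[mon] <- "MON"
  age_missing <- runif(n) < cfg$missing_age_rate
  age_rep[age_missing] <- NA_real_
  age_cod[age_missing] <- ""
  wt <- round(runif(n, 40, 120), 1)
  wt_cod <- rep("KG", n)
  wt_missing <- runif(n) < cfg$missing_weight_rate
  wt[wt_missing] <- NA_real_
  wt_cod[wt_missing] <- ""

  occp <- sample(c("CN", "MD", "OT", "HP", "PH", ""), n, replace = TRUE,
                 prob = c(0.783, 0.115, 0.051, 0.029, 0.014, 0.008))
  country <- sample(c("US", "PT", "FR", "ES", "CA", "GB", "DE"), n,
                    replace = TRUE,
                    prob = c(0.788, 0.089, 0.033, 0.024, 0.020, 0.025, 0.021))

  # therapy start, Weibull onset delay, event and receipt dates
  start_dt <- .rand_dates(n, "2014-01-01", "2023-06-30")
  tto_true <- pmax(1, ceiling(rweibull(n, cfg$tto_shape, cfg$tto_scale)))
  event_dt <- start_dt + tto_true
  fda_dt <- event_dt + floor(runif(n, 5, 120))

  start_str <- format_faers_date(start_dt)
  event_str <- format_faers_date(event_dt)
  corrupt <- runif(n) < cfg$date_error_rate
  which_field <- runif(n) < 0.5
  start_str[corrupt & which_field] <-
    substr(start_str[corrupt & which_field], 1, 6)
  event_str[corrupt & !which_field] <-
    substr(event_str[corrupt & !which_field], 1, 6)

  # report versions: v1 for everyone; a duplicate_rate slice gets a second
  # version — half later FDA_DT with a *lower* primaryid (date rule must win),
  # half equal FDA_DT with a higher primaryid (id rule must win).
  pid1 <- paste0(caseid, "1")
  dup <- runif(n) < cfg$duplicate_rate
  dup_equal <- dup & runif(n) < 0.5
  dup_later <- dup & !dup_equal

  surviving_pid <- pid1
  dup_pid <- character(n)
  dup_fda <- rep(as.Date(NA), n)
  dup_pid[dup_later] <- paste0(caseid[dup_later], "0")
  dup_fda[dup_later] <- fda_dt[dup_later] +
    floor(runif(sum(dup_later), 10, 200))
  surviving_pid[dup_later] <- dup_pid[dup_later]
  dup_pid[dup_equal] <- paste0(caseid[dup_equal], "2")
  dup_fda[dup_equal] <- fda_dt[dup_equal]
  surviving_pid[dup_equal] <- dup_pid[dup_equal]

  deleted <- sort(sample(caseid, floor(cfg$deleted_rate * n)))

  demo1 <- tibble::tibble(
    primaryid = pid1, caseid = caseid, caseversion = "1",
    fda_dt = format_faers_date(fda_dt), event_dt = event_str,
    sex = sex_rep, age = age_rep, age_cod = age_cod,
    wt = wt, wt_cod = wt_cod, occp_cod = occp,
    reporter_country = country)
  demo2 <- demo1[dup, ]
  demo2$primaryid <- dup_pid[dup]
  demo2$caseversion <- "2"
  demo2$fda_dt <- format_faers_date(dup_fda[dup])
  demo <- dplyr::arrange(dplyr::bind_rows(demo1, demo2), .data$caseid,
                         .data$caseversion)

  # drug rows: exactly one PS drug (seq 1) + 0-2 concomitants
  alias <- drug
  alias[is_target] <- sample(cfg$target_aliases, sum(is_target),
                             replace = TRUE)
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  con_roles <- c("SS", "C", "I")
  per_case_drugs <- function(pid_vec) {
    base <- tibble::tibble(
      primaryid = pid_vec, caseid = caseid, drug_seq = 1L,
      role_cod = "PS", drugname = alias,
      start_dt = start_str)
    con_idx <- rep(seq_len(n), n_con)
    if (!length(con_idx)) return(base)
    con <- tibble::tibble(
      primaryid = pid_vec[con_idx], caseid = caseid[con_idx],
      drug_seq = unlist(lapply(n_con[n_con > 0], function(k) 1L + seq_len(k))),
      role_cod = sample(con_roles, length(con_idx), replace = TRUE),
      drugname = sample(cfg$background_drugs, length(con_idx), replace = TRUE),
      start_dt = "")
    dplyr::bind_rows(base, con)
  }
  drug1 <- per_case_drugs(pid1)
  drug2 <- drug1[drug1$caseid %in% caseid[dup], ]
  drug2$primaryid <- dup_pid[match(drug2$caseid, caseid)]
  drug_tbl <- dplyr::arrange(dplyr::bind_rows(drug1, drug2),
                             .data$primaryid, .data$drug_seq)

  reac_idx <- which(draws, arr.ind = TRUE)
  reac1 <- tibble::tibble(
    primaryid = pid1[reac_idx[, 1]], caseid = caseid[reac_idx[, 1]],
    pt = pts[reac_idx[, 2]])
  # verbatim duplicate event rows at dup_pt_rate (must collapse downstream)
  dup_reac <- reac1[runif(nrow(reac1)) < cfg$dup_pt_rate, ]
  reac1 <- dplyr::bind_rows(reac1, dup_reac)
  reac2 <- reac1[reac1$caseid %in% caseid[dup], ]
  reac2$primaryid <- dup_pid[match(reac2$caseid, caseid)]
  reac <- dplyr::arrange(dplyr::bind_rows(reac1, reac2),
                         .data$primaryid, .data$pt)

  ther1 <- tibble::tibble(
    primaryid = pid1, caseid = caseid, dsg_drug_seq = 1L,
    start_dt = start_str)
  ther2 <- ther1[dup, ]
  ther2$primaryid <- dup_pid[dup]
  ther <- dplyr::arrange(dplyr::bind_rows(ther1, ther2), .data$primaryid)

  outc_codes <- c(DE = 0.026, HO = 0.138, DS = 0.010, CA = 0.005,
                  LT = 0.017, RI = 0.001, OT = 0.518)
  outc_draw <- matrix(runif(n * length(outc_codes)), n) <
    matrix(rep(outc_codes, each = n), nrow = n)
  oidx <- which(outc_draw, arr.ind = TRUE)
  outc1 <- tibble::tibble(
    primaryid = pid1[oidx[, 1]], caseid = caseid[oidx[, 1]],
    outc_cod = names(outc_codes)[oidx[, 2]])
  outc2 <- outc1[outc1$caseid %in% caseid[dup], ]
  outc2$primaryid <- dup_pid[match(outc2$caseid, caseid)]
  outc <- dplyr::arrange(dplyr::bind_rows(outc1, outc2),
                         .data$primaryid, .data$outc_cod)

  keep <- !(caseid %in% deleted)
  structure(list(
    demo = demo, drug = drug_tbl, reac = reac, ther = ther, outc = outc,
    deleted = deleted,
    ground_truth = list(
      planted = planted_truth,
      surviving = tibble::tibble(caseid = caseid[keep],
                                 primaryid = surviving_pid[keep]),
      deleted_caseids = deleted,
      n_cases = n,
      n_surviving = sum(keep),
      n_surviving_target = sum(keep & is_target),
      target_flag = tibble::tibble(caseid = caseid, is_target = is_target),
      sex_effects = as.list(cfg$sex_effects),
      age_effects = cfg$age_effects,
      tto_shape = cfg$tto_shape, tto_scale = cfg$tto_scale),
    quarter = cfg$quarter), class = "pv_synth_tables")
}

.empty_tables <- function() {
  structure(list(
    demo = tibble::tibble(primaryid = character(), caseid = character(),
                          caseversion = character(), fda_dt = character(),
                          event_dt = character(), sex = character(),
                          age = numeric(), age_cod = character(),
                          wt = numeric(), wt_cod = character(),
                          occp_cod = character(),
                          reporter_country = character()),
    drug = tibble::tibble(primaryid = character(), caseid = character(),
                          drug_seq = integer(), role_cod = character(),
                          drugname = character(), start_dt = character()),
    reac = tibble::tibble(primaryid = character(), caseid = character(),
                          pt = character()),
    ther = tibble::tibble(primaryid = character(), caseid = character(),
                          dsg_drug_seq = integer(), start_dt = character()),
    outc = tibble::tibble(primaryid = character(), caseid = character(),
                          outc_cod = character()),
    deleted = character(0)), class = "pv_synth_tables")
}

#' Write synthetic tables as FAERS-dialect ASCII files
#'
#' Emits `$`-delimited text files `DEMOyyQq.txt`, `DRUGyyQq.txt`,
#' `REACyyQq.txt`, `THERyyQq.txt`, `OUTCyyQq.txt`, a `deleted_cases.txt`
#' (one CASEID per line) and `ground_truth.json`. Writing the same tables
#' twice produces identical bytes.
#'
#' @param tables Output of [generate_tables()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(tables, dir) {
  stopifnot(inherits(tables, "pv_synth_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  q <- tables$quarter %||% "24Q1"
  paths <- c(
    demo = file.path(dir, paste0("DEMO", q, ".txt")),
    drug = file.path(dir, paste0("DRUG", q, ".txt")),
    reac = file.path(dir, paste0("REAC", q, ".txt")),
    ther = file.path(dir, paste0("THER", q, ".txt")),
    outc = file.path(dir, paste0("OUTC", q, ".txt")),
    deleted = file.path(dir, "deleted_cases.txt"))
  for (nm in c("demo", "drug", "reac", "ther", "outc")) {
    readr::write_delim(tables[[nm]], paths[[nm]], delim = "$", na = "")
  }
  writeLines(tables$deleted, paths[["deleted"]])
  if (!is.null(tables$ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(tables$ground_truth, gt_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}
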