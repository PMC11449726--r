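# Subgroup analyses within target-drug reports: sex-stratified reporting
# odds ratios, age-group assignment, and per-PT logistic regression (crude
# and age+sex adjusted odds ratios, adult group as reference).

#' Sex-stratified reporting odds ratio
#'
#' For each PT, a male-vs-female 2x2 within target-drug reports of known
#' sex: `a` = male reports with the PT, `b` = male reports without it,
#' `c`/`d` the same for female reports. The interval is the same Woolf
#' construction as [ror_stats()]; a PT is flagged sex-differential when the
#' interval excludes 1. A two-sided Fisher exact p with Bonferroni
#' correction across the tested PTs is included.
#'
#' @param dataset A `pv_dataset`.
#' @param pts Character vector of PTs to test (typically the
#'   combined-positive set).
#' @return Tibble with `pt`, cells `a`-`d`, `ror`, `ror_lo`, `ror_hi`,
#'   `p_raw`, `p_adj`, `estimable`, `sex_differential`.
#' @export
sex_ror <- function(dataset, pts) {
  stopifnot(inherits(dataset, "pv_dataset"))
  pts <- normalize_pt(pts)
  rep_known <- dataset$reports |>
    dplyr::filter(.data$target, .data$sex %in% c("F", "M"))
  ev <- dataset$events |>
    dplyr::filter(.data$primaryid %in% rep_known$primaryid)
  n_m <- sum(rep_known$sex == "M")
  n_f <- sum(rep_known$sex == "F")
  male_pids <- rep_known$primaryid[rep_known$sex == "M"]
  cells <- purrr::map_dfr(pts, function(pt) {
    with_pt <- ev$primaryid[ev$pt == pt]
    a <- sum(with_pt %in% male_pids)
    c <- length(with_pt) - a
    tibble::tibble(pt = pt, a = a, b = n_m - a, c = c, d = n_f - c)
  })
  est <- ror_stats(cells$a, cells$b, cells$c, cells$d)
  p_raw <- .fisher_p(cells$a, cells$b, cells$c, cells$d)
  m <- max(1L, nrow(cells))
  dplyr::bind_cols(cells, est) |>
    dplyr::mutate(
      p_raw = p_raw,
      p_adj = pmin(1, m * p_raw),
      estimable = !is.na(.data$ror),
      sex_differential = .data$estimable &
        (.data$ror_lo > 1 | .data$ror_hi < 1))
}

#' Assign the age group used for stratified analysis
#'
#' `children` below 18 years, `adult` from 18 up to (not including) 65,
#' `elderly` from 65, `unknown` for missing ages.
#'
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Character vector of group labels.
#' @export
assign_age_group <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "children",
    age_years < 65 ~ "adult",
    TRUE ~ "elderly")
}

#' Per-PT logistic regression odds ratios across age groups
#'
#' Restricted to target-drug reports with known age and sex. For each PT the
#' outcome is presence of the PT on the report; the crude model regresses on
#' the age-group factor alone (adult reference) and the adjusted model adds
#' sex. Odds ratios are exponentiated coefficients with Wald 95% intervals.
#' A contrast is estimable only when both its arm and the adult arm contain
#' at least one event and one non-event; inestimable contrasts carry `NA`
#' estimates and `estimable = FALSE` (the way forest plots leave out
#' strata with too few cases).
#'
#' @param dataset A `pv_dataset`.
#' @param pts PTs to model (typically the combined-positive set).
#' @param adjust Include the sex-adjusted model (default `TRUE`).
#' @return Tibble with one row per PT x contrast
#'   (`children_vs_adult`, `elderly_vs_adult`): event counts per arm,
#'   `crude_or`, `crude_lo`, `crude_hi`, `crude_p`, `adj_or`, `adj_lo`,
#'   `adj_hi`, `adj_p`, `estimable`, `reason`.
#' @export
logistic_or <- function(dataset, pts, adjust = TRUE) {
  stopifnot(inherits(dataset, "pv_dataset"))
  pts <- normalize_pt(pts)
  frame <- dataset$reports |>
    dplyr::filter(.data$target, .data$sex %in% c("F", "M"),
                  !is.na(.data$age_years)) |>
    dplyr::mutate(age_group = factor(assign_age_group(.data$age_years),
                                     levels = c("adult", "children",
                                                "elderly")),
                  sex = factor(.data$sex, levels = c("F", "M")))
  contrasts <- c(children = "children_vs_adult", elderly = "elderly_vs_adult")
  purrr::map_dfr(pts, function(pt) {
    with_pt <- dataset$events$primaryid[dataset$events$pt == pt]
    dat <- dplyr::mutate(frame, y = .data$primaryid %in% with_pt)
    arm_ok <- vapply(c("adult", "children", "elderly"), function(g) {
      yy <- dat$y[dat$age_group == g]
      length(yy) > 0 && any(yy) && !all(yy)
    }, logical(1))
    ev_n <- vapply(c("adult", "children", "elderly"),
                   function(g) sum(dat$y[dat$age_group == g]), numeric(1))
    base <- tibble::tibble(
      pt = pt,
      contrast = unname(contrasts),
      group = names(contrasts),
      n_events_group = ev_n[names(contrasts)],
      n_events_adult = ev_n[["adult"]],
      crude_or = NA_real_, crude_lo = NA_real_, crude_hi = NA_real_,
      crude_p = NA_real_,
      adj_or = NA_real_, adj_lo = NA_real_, adj_hi = NA_real_,
      adj_p = NA_real_,
      estimable = arm_ok[["adult"]] & arm_ok[names(contrasts)],
      reason = dplyr::if_else(arm_ok[["adult"]] & arm_ok[names(contrasts)],
                              "", "zero_events_in_arm"))
    if (!any(base$estimable)) return(dplyr::select(base, -"group"))
    ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
    fit_one <- function(formula) {
      fit <- tryCatch(
        suppressWarnings(stats::glm(formula, data = dat, family = binomial(),
                                    control = ctrl)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) return(NULL)
      fit
    }
    extract <- function(fit, term) {
      if (is.null(fit) || !(term %in% names(coef(fit)))) {
        return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      }
      est <- coef(fit)[[term]]
      se <- sqrt(diag(vcov(fit))[[term]])
      p <- 2 * stats::pnorm(-abs(est / se))
      c(exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se), p)
    }
    crude <- fit_one(y ~ age_group)
    adj <- if (adjust) fit_one(y ~ age_group + sex) else NULL
    for (k in seq_len(nrow(base))) {
      if (!base$estimable[k]) next
      term <- paste0("age_group", base$group[k])
      cv <- extract(crude, term)
      base[k, c("crude_or", "crude_lo", "crude_hi", "crude_p")] <- as.list(cv)
      if (adjust) {
        av <- extract(adj, term)
        base[k, c("adj_or", "adj_lo", "adj_hi", "adj_p")] <- as.list(av)
      }
      if (is.null(crude)) {
        base$estimable[k] <- FALSE
        base$reason[k] <- "nonconvergence"
      }
    }
    dplyr::select(base, -"group")
  })
}
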