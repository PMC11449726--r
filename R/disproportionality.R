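# Disproportionality estimators on 2x2 contingency tables and the
# four-algorithm combined signal call.
#
# The 2x2 for one PT, counted at the event-record level (one record = one
# distinct (report, PT) pair):
#
#                 with PT   other PTs   total
#   target drug      a          b        a+b
#   other drugs      c          d        c+d
#                   a+c        b+d        N
#
# Signal standards: ROR needs a >= 3 and the lower 95% CI bound > 1; PRR the
# same on its own CI; BCPNN needs a >= 3 and E(IC) - 2*sqrt(V(IC)) > 0; the
# empirical Bayes geometric mean needs a > 0 and EBGM05 > 2. A PT is a
# combined positive only when all four fire.

#' BCPNN prior hyperparameters
#'
#' Beta/Dirichlet priors of the closed-form BCPNN information component.
#' Defaults are the conventional `alpha = beta = 2`,
#' `alpha_i = beta_j = gamma_ij = 1`.
#'
#' @param alpha,beta,alpha_i,beta_j,gamma_ij Positive reals.
#' @return Named list of class `pv_bcpnn_hyper`.
#' @export
bcpnn_hyperparams <- function(alpha = 2, beta = 2, alpha_i = 1, beta_j = 1,
                              gamma_ij = 1) {
  vals <- c(alpha, beta, alpha_i, beta_j, gamma_ij)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("all BCPNN hyperparameters must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, alpha_i = alpha_i,
                 beta_j = beta_j, gamma_ij = gamma_ij),
            class = "pv_bcpnn_hyper")
}

#' Per-PT 2x2 contingency cells for the target drug
#'
#' Counts at the event-record level: `a` is the number of distinct (target
#' report, PT) pairs for the PT, `a + b` the target drug's total record
#' count, and likewise `c`, `d` for all other drugs, so the margins are
#' constant across PTs.
#'
#' @param dataset A `pv_dataset` from [assemble_dataset()].
#' @param pts Optional character vector of PTs to tabulate; defaults to
#'   every PT observed on a target-drug report.
#' @return Tibble with `pt`, `a`, `b`, `c`, `d`, `n`.
#' @export
pt_contingency <- function(dataset, pts = NULL) {
  stopifnot(inherits(dataset, "pv_dataset"))
  ev <- dataset$events |>
    dplyr::inner_join(dplyr::select(dataset$reports, "primaryid", "target"),
                      by = "primaryid")
  tot_target <- sum(ev$target)
  tot_other <- sum(!ev$target)
  counts <- ev |>
    dplyr::count(.data$pt, .data$target) |>
    tidyr::pivot_wider(names_from = "target", values_from = "n",
                       values_fill = 0L)
  if (!"TRUE" %in% names(counts)) counts[["TRUE"]] <- 0L
  if (!"FALSE" %in% names(counts)) counts[["FALSE"]] <- 0L
  counts <- dplyr::rename(counts, a = "TRUE", c = "FALSE")
  if (is.null(pts)) {
    pts <- sort(counts$pt[counts$a > 0])
  } else {
    pts <- normalize_pt(pts)
  }
  tibble::tibble(pt = pts) |>
    dplyr::left_join(counts, by = "pt") |>
    dplyr::mutate(a = dplyr::coalesce(.data$a, 0L),
                  c = dplyr::coalesce(.data$c, 0L),
                  b = tot_target - .data$a,
                  d = tot_other - .data$c,
                  n = .data$a + .data$b + .data$c + .data$d) |>
    dplyr::select("pt", "a", "b", "c", "d", "n")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`, with the Woolf interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the estimate and interval `NA` (no continuity correction by default).
#'
#' @param a,b,c,d Numeric vectors of cell counts.
#' @return Tibble with `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d) {
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  est <- ifelse(defined, (a * d) / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(ror = est,
                 ror_lo = exp(log(est) - 1.96 * se),
                 ror_hi = exp(log(est) + 1.96 * se))
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Undefined
#' (`NA`) when `a`, `c` or a margin is zero.
#'
#' @inheritParams ror_stats
#' @return Tibble with `prr`, `prr_lo`, `prr_hi`.
#' @export
prr_stats <- function(a, b, c, d) {
  defined <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  est <- ifelse(defined, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(defined,
               sqrt(pmax(0, 1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))),
               NA_real_)
  tibble::tibble(prr = est,
                 prr_lo = exp(log(est) - 1.96 * se),
                 prr_hi = exp(log(est) + 1.96 * se))
}

#' BCPNN information component with posterior moments
#'
#' Closed-form information component `IC = log2[a*N / ((a+b)(a+c))]` and its
#' posterior expectation and variance under Beta/Dirichlet priors:
#' \deqn{\gamma = \gamma_{ij}(N+\alpha)(N+\beta) /
#'   [(a+b+\alpha_i)(a+c+\beta_j)]}
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{ij})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_i)(a+c+\beta_j)}}
#' \deqn{V(IC) = (\ln 2)^{-2}\left[
#'   \frac{N-a+\gamma-\gamma_{ij}}{(a+\gamma_{ij})(1+N+\gamma)} +
#'   \frac{N-a-b+\alpha-\alpha_i}{(a+b+\alpha_i)(1+N+\alpha)} +
#'   \frac{N-a-c+\beta-\beta_j}{(a+c+\beta_j)(1+N+\beta)}\right]}
#' The signal bound is `E(IC) - 2*sqrt(V(IC))`. The observed IC is `NA` when
#' `a = 0` (the posterior moments stay finite through the priors).
#'
#' @inheritParams ror_stats
#' @param hyper A [bcpnn_hyperparams()].
#' @return Tibble with `ic`, `e_ic`, `v_ic`, `ic_minus_2sd`.
#' @export
bcpnn_stats <- function(a, b, c, d, hyper = bcpnn_hyperparams()) {
  n <- a + b + c + d
  ic <- ifelse(a > 0 & (a + b) > 0 & (a + c) > 0,
               log2(a * n / ((a + b) * (a + c))), NA_real_)
  g <- hyper$gamma_ij * (n + hyper$alpha) * (n + hyper$beta) /
    ((a + b + hyper$alpha_i) * (a + c + hyper$beta_j))
  e_ic <- log2((a + hyper$gamma_ij) * (n + hyper$alpha) * (n + hyper$beta) /
                 ((n + g) * (a + b + hyper$alpha_i) * (a + c + hyper$beta_j)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + g - hyper$gamma_ij) / ((a + hyper$gamma_ij) * (1 + n + g)) +
      (n - a - b + hyper$alpha - hyper$alpha_i) /
        ((a + b + hyper$alpha_i) * (1 + n + hyper$alpha)) +
      (n - a - c + hyper$beta - hyper$beta_j) /
        ((a + c + hyper$beta_j) * (1 + n + hyper$beta)))
  tibble::tibble(ic = ic, e_ic = e_ic, v_ic = v_ic,
                 ic_minus_2sd = e_ic - 2 * sqrt(v_ic))
}

#' Empirical Bayes geometric mean (relative reporting ratio form)
#'
#' The default `corrected` dialect is the relative reporting ratio
#' `EBGM = a*N / ((a+b)(a+c))`, which equals 1 under exact independence.
#' The `as_printed` dialect `a*N / ((a+c)(b+d))` is also available; it does
#' not satisfy the independence property and is provided only for
#' comparison with sources that print it. Both use
#' `EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams ror_stats
#' @param dialect `"corrected"` (default) or `"as_printed"`.
#' @return Tibble with `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, b, c, d, dialect = c("corrected", "as_printed")) {
  dialect <- match.arg(dialect)
  n <- a + b + c + d
  est <- if (dialect == "corrected") {
    ifelse(a > 0 & (a + b) > 0 & (a + c) > 0,
           a * n / ((a + b) * (a + c)), NA_real_)
  } else {
    ifelse(a > 0 & (a + c) > 0 & (b + d) > 0,
           a * n / ((a + c) * (b + d)), NA_real_)
  }
  se <- ifelse(a > 0 & b > 0 & c > 0 & d > 0,
               sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(ebgm = est, ebgm05 = exp(log(est) - 1.96 * se))
}

# Two-sided Fisher exact p for vectors of 2x2 cells.
.fisher_p <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    m <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE)
    if (any(!is.finite(m)) || any(m < 0)) return(NA_real_)
    stats::fisher.test(m)$p.value
  }, numeric(1))
}

#' All four disproportionality algorithms with signal flags
#'
#' Takes a cell table (from [pt_contingency()] or built by hand), computes
#' ROR, PRR, the BCPNN information component and the EBGM with their
#' intervals/bounds, a two-sided Fisher exact p-value with Bonferroni
#' correction, the per-algorithm flags and the combined four-way call.
#'
#' @param counts Data frame with columns `a`, `b`, `c`, `d` (and usually
#'   `pt`).
#' @param hyper BCPNN priors, see [bcpnn_hyperparams()].
#' @param dialect EBGM dialect, see [ebgm_stats()].
#' @param m_tests Bonferroni multiplier; defaults to the number of rows
#'   with `a >= 1` (distinct PTs observed for the target drug).
#' @param fisher Compute Fisher exact p-values (`TRUE` by default; turn off
#'   for bulk calibration runs where only flags matter).
#' @return The input tibble extended with estimator columns, `p_raw`,
#'   `p_adj`, and logical `ror_pos`, `prr_pos`, `bcpnn_pos`, `mgps_pos`,
#'   `combined_pos`. The Bonferroni `m` used is stored in attribute
#'   `m_tests`.
#' @export
signal_metrics <- function(counts, hyper = bcpnn_hyperparams(),
                           dialect = c("corrected", "as_printed"),
                           m_tests = NULL, fisher = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  counts <- tibble::as_tibble(counts)
  a <- counts$a; b <- counts$b; c <- counts$c; d <- counts$d
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stop("contingency cells must be nonnegative", call. = FALSE)
  }
  m <- m_tests %||% max(1L, sum(a >= 1))
  if (m < 1) stop("`m_tests` must be >= 1", call. = FALSE)
  out <- dplyr::bind_cols(
    counts,
    ror_stats(a, b, c, d),
    prr_stats(a, b, c, d),
    bcpnn_stats(a, b, c, d, hyper),
    ebgm_stats(a, b, c, d, dialect))
  if (fisher) {
    out$p_raw <- .fisher_p(a, b, c, d)
    out$p_adj <- pmin(1, m * out$p_raw)
  } else {
    out$p_raw <- NA_real_
    out$p_adj <- NA_real_
  }
  out <- out |>
    dplyr::mutate(
      ror_pos = .data$a >= 3 & !is.na(.data$ror_lo) & .data$ror_lo > 1,
      prr_pos = .data$a >= 3 & !is.na(.data$prr_lo) & .data$prr_lo > 1,
      bcpnn_pos = .data$a >= 3 & .data$ic_minus_2sd > 0,
      mgps_pos = .data$a > 0 & !is.na(.data$ebgm05) & .data$ebgm05 > 2,
      combined_pos = .data$ror_pos & .data$prr_pos & .data$bcpnn_pos &
        .data$mgps_pos)
  attr(out, "m_tests") <- m
  out
}

#' Volcano-plot coordinates for signal metrics
#'
#' One row per PT with a defined ROR: `log2(ROR)` against
#' `-log10(p_adj)`.
#'
#' @param metrics Output of [signal_metrics()].
#' @return Tibble with `pt`, `log2_ror`, `neg_log10_p_adj`, `combined_pos`.
#' @export
volcano_table <- function(metrics) {
  metrics |>
    dplyr::filter(!is.na(.data$ror)) |>
    dplyr::transmute(pt = .data$pt,
                     log2_ror = log2(.data$ror),
                     neg_log10_p_adj = -log10(.data$p_adj),
                     combined_pos = .data$combined_pos)
}

#' Group-level disproportionality (SOC or narrow SMQ)
#'
#' Re-builds contingency cells at the group level — `a` is the number of
#' distinct (report, group) pairs on target reports — and runs
#' [signal_metrics()]. For `level = "smq"` only narrow-scope memberships are
#' used and, following usual practice, aggregation is restricted to a given
#' positive PT set with member-PT and record counts reported per SMQ.
#' PTs without a mapping fall into an `"UNMAPPED"` group.
#'
#' @param dataset A `pv_dataset`.
#' @param maps A `pv_term_maps`.
#' @param level `"soc"` or `"smq"`.
#' @param positive_pts For `level = "smq"`: the combined-positive PT set to
#'   group (required).
#' @param hyper,dialect,m_tests Passed to [signal_metrics()]; `m_tests`
#'   defaults to the number of groups observed for the target drug.
#' @return For `"soc"`: a signal-metrics tibble keyed by `group`. For
#'   `"smq"`: the same plus `n_member_pts` and `member_pts`.
#' @export
aggregate_by_group <- function(dataset, maps, level = c("soc", "smq"),
                               positive_pts = NULL,
                               hyper = bcpnn_hyperparams(),
                               dialect = "corrected", m_tests = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(dataset, "pv_dataset"), inherits(maps, "pv_term_maps"))
  ev <- dataset$events |>
    dplyr::inner_join(dplyr::select(dataset$reports, "primaryid", "target"),
                      by = "primaryid")
  if (level == "soc") {
    mapping <- dplyr::select(maps$pt_to_soc, "pt", group = "soc_name")
    ev_g <- ev |>
      dplyr::left_join(mapping, by = "pt", relationship = "many-to-many") |>
      dplyr::mutate(group = dplyr::coalesce(.data$group, "UNMAPPED"))
  } else {
    if (is.null(positive_pts)) {
      stop("`positive_pts` is required for SMQ aggregation", call. = FALSE)
    }
    mapping <- maps$pt_to_smq |>
      dplyr::filter(.data$scope == "narrow") |>
      dplyr::select("pt", group = "smq_name")
    ev_g <- ev |>
      dplyr::filter(.data$pt %in% normalize_pt(positive_pts)) |>
      dplyr::inner_join(mapping, by = "pt", relationship = "many-to-many")
  }
  ev_g <- dplyr::distinct(ev_g, .data$primaryid, .data$target, .data$group,
                          .keep_all = TRUE)
  # margins: distinct (report, group) pairs per stratum
  tot_target <- sum(ev_g$target)
  tot_other <- sum(!ev_g$target)
  cells <- ev_g |>
    dplyr::count(.data$group, .data$target) |>
    tidyr::pivot_wider(names_from = "target", values_from = "n",
                       values_fill = 0L)
  if (!"TRUE" %in% names(cells)) cells[["TRUE"]] <- 0L
  if (!"FALSE" %in% names(cells)) cells[["FALSE"]] <- 0L
  cells <- cells |>
    dplyr::rename(a = "TRUE", c = "FALSE") |>
    dplyr::mutate(b = tot_target - .data$a, d = tot_other - .data$c,
                  n = .data$a + .data$b + .data$c + .data$d) |>
    dplyr::filter(.data$a > 0) |>
    dplyr::arrange(.data$group)
  out <- signal_metrics(cells, hyper = hyper, dialect = dialect,
                        m_tests = m_tests)
  if (level == "smq") {
    # per SMQ: how many positive member PTs map into it, and the target-drug
    # record count (a) already carried in the cells
    member_info <- mapping |>
      dplyr::filter(.data$pt %in% normalize_pt(positive_pts)) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n_member_pts = dplyr::n_distinct(.data$pt),
                       member_pts = paste(sort(unique(.data$pt)),
                                          collapse = "; "),
                       .groups = "drop")
    out <- dplyr::left_join(out, member_info, by = "group")
  }
  out
}
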