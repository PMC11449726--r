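# Shared fixture builders. Everything is constructed in code; no stored data.

# A raw quarter built from hand-written rows, in the all-character form
# read_quarter() returns. Missing tables default to empty.
toy_raw <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                    outc = NULL, deleted = character(0)) {
  blank <- pvkit:::.empty_tables()
  as_chr <- function(x, template) {
    if (is.null(x)) return(dplyr::mutate(template, dplyr::across(
      dplyr::everything(), as.character)))
    x <- tibble::as_tibble(x)
    dplyr::mutate(x, dplyr::across(dplyr::everything(),
                                   ~ dplyr::coalesce(as.character(.x), "")))
  }
  structure(list(demo = as_chr(demo, blank$demo),
                 drug = as_chr(drug, blank$drug),
                 reac = as_chr(reac, blank$reac),
                 ther = as_chr(ther, blank$ther),
                 outc = as_chr(outc, blank$outc),
                 deleted = as.character(deleted)),
            class = "pv_raw_quarter")
}

# One-report-per-row demo builder.
toy_demo <- function(caseid, primaryid, fda_dt, sex = "F", age = NA,
                     age_cod = "YR", event_dt = "", wt = NA) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 caseversion = "1",
                 fda_dt = as.character(fda_dt),
                 event_dt = as.character(event_dt),
                 sex = sex, age = age, age_cod = age_cod,
                 wt = wt, wt_cod = ifelse(is.na(wt), "", "KG"),
                 occp_cod = "CN", reporter_country = "US")
}

toy_drug <- function(primaryid, drugname, role_cod = "PS", drug_seq = 1) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(primaryid),
                 drug_seq = drug_seq, role_cod = role_cod,
                 drugname = drugname, start_dt = "")
}

toy_reac <- function(primaryid, pt) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(primaryid), pt = pt)
}

esl_synonyms <- function() load_synonyms()

# A small but complete synthetic configuration used across tests.
small_config <- function(seed = 7, n_cases = 800, ...) {
  synthetic_config(n_cases = n_cases, seed = seed, ...)
}

# Independent brute-force transcription of the four estimator formulas,
# written against scalar arithmetic (no shared code with the package path).
oracle_metrics <- function(a, b, c, d, alpha = 2, beta = 2, alpha_i = 1,
                           beta_j = 1, gamma_ij = 1) {
  N <- a + b + c + d
  ror <- (a * d) / (b * c)
  ror_se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a * (c + d)) / (c * (a + b))
  prr_se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  ic <- log(a * N / ((a + b) * (a + c)), base = 2)
  g <- gamma_ij * (N + alpha) * (N + beta) /
    ((a + b + alpha_i) * (a + c + beta_j))
  e_ic <- log((a + gamma_ij) * (N + alpha) * (N + beta) /
                ((N + g) * (a + b + alpha_i) * (a + c + beta_j)), base = 2)
  v_ic <- (log(2))^(-2) * (
    (N - a + g - gamma_ij) / ((a + gamma_ij) * (1 + N + g)) +
      (N - a - b + alpha - alpha_i) / ((a + b + alpha_i) * (1 + N + alpha)) +
      (N - a - c + beta - beta_j) / ((a + c + beta_j) * (1 + N + beta)))
  ebgm <- a * N / ((a + b) * (a + c))
  ebgm_printed <- a * N / ((a + c) * (b + d))
  list(ror = ror,
       ror_lo = exp(log(ror) - 1.96 * ror_se),
       ror_hi = exp(log(ror) + 1.96 * ror_se),
       prr = prr,
       prr_lo = exp(log(prr) - 1.96 * prr_se),
       prr_hi = exp(log(prr) + 1.96 * prr_se),
       ic = ic, e_ic = e_ic, v_ic = v_ic,
       ic_minus_2sd = e_ic - 2 * sqrt(v_ic),
       ebgm = ebgm, ebgm_printed = ebgm_printed,
       ebgm05 = exp(log(ebgm) - 1.96 * ror_se),
       ebgm05_printed = exp(log(ebgm_printed) - 1.96 * ror_se))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b       # margin of the exposed row
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
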