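# Small shared helpers: name/term normalisation, FAERS CCYYMMDD dates, odds.

#' Normalise a drug name for dictionary matching
#'
#' Upper-cases, replaces runs of whitespace/punctuation with a single space,
#' and trims. `"  aptiom "` and `"APTIOM"` normalise identically.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalised names.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

#' Normalise a MedDRA preferred term
#'
#' Upper-cases, collapses internal whitespace, trims.
#'
#' @param x Character vector of PT strings.
#' @return Character vector of normalised PTs.
#' @export
normalize_pt <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Classify a FAERS CCYYMMDD date string: "complete" (8 digits, parses),
# "partial" (4 or 6 digits), "missing" (empty/NA), "invalid" (anything else,
# incl. 8-digit strings that are not real dates).
classify_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("invalid", length(x))
  out[is.na(x) | x == ""] <- "missing"
  part <- !is.na(x) & grepl("^[0-9]{4}$|^[0-9]{6}$", x)
  out[part] <- "partial"
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(full)) {
    parsed <- as.Date(x[full], format = "%Y%m%d")
    out[full][!is.na(parsed)] <- "complete"
  }
  out
}

parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  ok <- classify_faers_date(x) == "complete"
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

format_faers_date <- function(d) format(d, "%Y%m%d")

odds_of <- function(p) p / (1 - p)

inv_odds <- function(o) o / (1 + o)

# Multiply the odds of probability p by `or`, return the new probability.
shift_odds <- function(p, or) inv_odds(odds_of(p) * or)

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
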