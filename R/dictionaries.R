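# Term maps: PT -> SOC, PT -> SMQ (with scope), the designated-medical-event
# list, and the drug-label PT list. MedDRA content is licensed, so the
# package defines an open CSV format and ships a synthetic mini-dictionary
# covering the terms the bundled generator uses.

#' Load term maps from the open CSV format
#'
#' Three CSVs plus two plain-text lists:
#' * `pt_soc`: columns `pt`, `soc_name`, `soc_code` — each PT maps to
#'   exactly one (primary) SOC; conflicting duplicates are an error.
#' * `pt_smq`: columns `pt`, `smq_name`, `smq_code`, `scope`
#'   (`narrow`/`broad`) — a PT may belong to several SMQs.
#' * `dme`: one PT per line, the designated-medical-event list.
#' * `label_pts`: one PT per line, events listed in the drug label
#'   ("instructions included"); user-supplied metadata, never computed.
#'
#' @param pt_soc,pt_smq,dme,label_pts File paths; defaults are the bundled
#'   synthetic mini-dictionary.
#' @return List of class `pv_term_maps` with tibbles `pt_to_soc`,
#'   `pt_to_smq` and character sets `dme_list`, `label_pts`.
#' @export
load_term_maps <- function(
    pt_soc = system.file("extdata", "pt_soc.synthetic.csv", package = "pvkit"),
    pt_smq = system.file("extdata", "pt_smq.synthetic.csv", package = "pvkit"),
    dme = system.file("extdata", "dme_list.synthetic.txt", package = "pvkit"),
    label_pts = system.file("extdata", "label_pts.synthetic.txt",
                            package = "pvkit")) {
  soc <- readr::read_csv(pt_soc, col_types = "ccc", progress = FALSE) |>
    dplyr::mutate(pt = normalize_pt(.data$pt)) |>
    dplyr::distinct()
  if (nrow(soc)) {
    stopifnot(all(c("pt", "soc_name", "soc_code") %in% names(soc)))
    conflict <- soc |>
      dplyr::count(.data$pt) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflict)) {
      stop("PT(s) mapped to more than one SOC: ",
           paste(conflict$pt, collapse = ", "), call. = FALSE)
    }
  }
  smq <- readr::read_csv(pt_smq, col_types = "cccc", progress = FALSE) |>
    dplyr::mutate(pt = normalize_pt(.data$pt),
                  scope = tolower(trimws(.data$scope))) |>
    dplyr::distinct()
  if (nrow(smq)) {
    stopifnot(all(c("pt", "smq_name", "smq_code", "scope") %in% names(smq)))
    bad <- setdiff(unique(smq$scope), c("narrow", "broad"))
    if (length(bad)) {
      stop("unknown SMQ scope value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    narrow_missing <- setdiff(smq$pt[smq$scope == "narrow"], soc$pt)
    if (length(narrow_missing)) {
      stop("narrow-SMQ PT(s) absent from the SOC map: ",
           paste(narrow_missing, collapse = ", "), call. = FALSE)
    }
  }
  read_set <- function(path) {
    x <- readLines(path)
    x <- trimws(sub("#.*$", "", x))
    unique(normalize_pt(x[nzchar(x)]))
  }
  structure(list(pt_to_soc = soc, pt_to_smq = smq,
                 dme_list = read_set(dme), label_pts = read_set(label_pts)),
            class = "pv_term_maps")
}

#' Screen signal-positive PTs against the designated-medical-event list
#'
#' Intersects the combined-positive PT set with the DME list, and also
#' reports same-SOC companion positives: any other positive PT sharing a
#' SOC with a matched DME (the way a skin-disorder DME match pulls in the
#' rest of the positive skin terms).
#'
#' @param metrics Signal metrics tibble from [signal_metrics()] (needs
#'   `pt`, `a`, `ror`, `ror_lo`, `combined_pos`).
#' @param maps A `pv_term_maps`.
#' @return Tibble with `pt`, `a`, `ror`, `ror_lo`, `soc_name`, `dme_match`
#'   (logical), `label_listed` (logical), sorted DME matches first then by
#'   descending ROR.
#' @export
screen_dme <- function(metrics, maps) {
  stopifnot(inherits(maps, "pv_term_maps"))
  pos <- dplyr::filter(metrics, .data$combined_pos)
  if (nrow(pos) == 0) {
    return(tibble::tibble(pt = character(), a = numeric(), ror = numeric(),
                          ror_lo = numeric(), soc_name = character(),
                          dme_match = logical(), label_listed = logical()))
  }
  pos <- pos |>
    dplyr::left_join(maps$pt_to_soc, by = "pt") |>
    dplyr::mutate(dme_match = .data$pt %in% maps$dme_list)
  dme_socs <- unique(pos$soc_name[pos$dme_match & !is.na(pos$soc_name)])
  pos |>
    dplyr::filter(.data$dme_match |
                    (!is.na(.data$soc_name) & .data$soc_name %in% dme_socs)) |>
    dplyr::mutate(label_listed = .data$pt %in% maps$label_pts) |>
    dplyr::arrange(dplyr::desc(.data$dme_match), dplyr::desc(.data$ror)) |>
    dplyr::select("pt", "a", "ror", "ror_lo", "soc_name", "dme_match",
                  "label_listed")
}
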