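#' Load a PT to SOC vocabulary
#'
#' Reads a vocabulary table mapping MedDRA Preferred Terms (PTs) to System
#' Organ Classes (SOCs). The package ships a toy vocabulary of ~50 infant
#' adverse-event PTs across 13 SOCs with per-report baseline reporting
#' probabilities (used by the synthetic generator); a real MedDRA table can
#' be supplied as a CSV with columns `pt`, `soc` and optionally `baseline`.
#'
#' @param path path to a CSV with columns `pt`, `soc` (and optionally
#'   `baseline`); `NULL` loads the bundled toy vocabulary.
#' @return a tibble with columns `pt`, `soc` and, when present, `baseline`.
#' @export
load_pt_vocab <- function(path = NULL) {
  path <- path %||% system.file("extdata", "toy_meddra.csv",
    package = "aefisignal", mustWork = TRUE
  )
  vocab <- readr::read_csv(path, col_types = readr::cols(
    pt = readr::col_character(), soc = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("pt", "soc") %in% names(vocab))) {
    stop("vocabulary file ", path, " must have columns 'pt' and 'soc'")
  }
  if (anyDuplicated(vocab$pt)) {
    stop("vocabulary maps some PT to more than one SOC: ",
      paste(unique(vocab$pt[duplicated(vocab$pt)]), collapse = ", "))
  }
  vocab
}

#' Map Preferred Terms to System Organ Classes
#'
#' Vectorized lookup of the SOC for each PT. PTs absent from the vocabulary
#' map to the designated `"Unmapped"` SOC with a warning, so analyses never
#' silently drop events.
#'
#' @param pt character vector of PT labels.
#' @param vocab vocabulary tibble from [load_pt_vocab()].
#' @return character vector of SOC labels.
#' @export
map_pt_to_soc <- function(pt, vocab) {
  soc <- vocab$soc[match(pt, vocab$pt)]
  unknown <- is.na(soc)
  if (any(unknown)) {
    warning("PT(s) not in vocabulary mapped to 'Unmapped': ",
      paste(unique(pt[unknown]), collapse = ", "), call. = FALSE)
    soc[unknown] <- "Unmapped"
  }
  soc
}

#' Default vaccination-error Preferred Terms
#'
#' PTs describing administration errors rather than clinical adverse events.
#' Reports whose entire PT set lies in this list are excluded from the cohort
#' (error-only reports describe no adverse event following immunization).
#'
#' @return character vector of PT labels.
#' @export
default_error_pts <- function() {
  c(
    "Incorrect dose administered",
    "Wrong product administered",
    "Expired product administered",
    "Product preparation issue",
    "Incomplete course of vaccination",
    "Inappropriate schedule of product administration"
  )
}
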