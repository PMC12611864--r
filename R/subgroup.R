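# Stratified analyses: the full contingency + disproportionality machinery
# applied within strata of age group, sex or seriousness, plus the ranked
# top-K most-frequent-PT table with per-stratum RORs.

STRATA_FACTORS <- c("age_group", "sex", "serious")

#' Split a cohort into strata
#'
#' Partitions the report collection by one stratification factor. Missing
#' values form their own `"missing"` stratum rather than being dropped.
#'
#' @param reports analysis-ready report tibble.
#' @param factor one of `"age_group"`, `"sex"`, `"serious"`.
#' @return named list of report tibbles; the names are the stratum levels.
#' @export
stratify <- function(reports, factor = STRATA_FACTORS) {
  factor <- match.arg(factor)
  values <- reports[[factor]]
  if (factor == "serious") {
    values <- ifelse(values, "serious", "non_serious")
  }
  values <- as.character(values)
  values[is.na(values)] <- "missing"
  split(reports, values)
}

#' Per-stratum signal analysis
#'
#' Runs [build_all_tables()] and [compute_signals()] within each stratum of
#' the given factor, with the comparator drawn from the same stratum (the
#' stratification is the confounding control). Strata where the target or
#' comparator class has no reports are skipped with a warning.
#'
#' @inheritParams stratify
#' @param level `"PT"` or `"SOC"`.
#' @param target_class `"penta"` or `"hexa"`.
#' @param prior optional shared [mgps_prior()]; default fits per stratum.
#' @return tibble of signal results with a leading `stratum` column.
#' @export
subgroup_signals <- function(reports, factor = STRATA_FACTORS,
                             level = c("PT", "SOC"),
                             target_class = c("hexa", "penta"),
                             prior = NULL) {
  factor <- match.arg(factor)
  level <- match.arg(level)
  target_class <- match.arg(target_class)
  strata <- stratify(reports, factor)
  out <- lapply(names(strata), function(s) {
    sub <- strata[[s]]
    if (!any(sub$vaccine_class == target_class) ||
        !any(sub$vaccine_class != target_class)) {
      warning("subgroup_signals: stratum '", s,
        "' lacks target or comparator reports; skipped", call. = FALSE)
      return(NULL)
    }
    tables <- build_all_tables(sub, level = level, target_class = target_class)
    res <- compute_signals(tables, prior = prior)
    dplyr::bind_cols(tibble::tibble(stratum = s), res)
  })
  dplyr::bind_rows(out)
}

#' Top-K most frequently reported PTs with RORs
#'
#' Ranks PTs by descending report count in the target class (ties broken
#' alphabetically) within an optional stratum, and attaches each PT's ROR
#' with its 95% CI computed against the comparator class within the same
#' stratum. If fewer than `k` distinct PTs occur, the full list is
#' returned without padding.
#'
#' @inheritParams subgroup_signals
#' @param k number of PTs to keep (>= 1).
#' @param stratum optional `list(factor = , level = )` restricting the
#'   cohort to one stratum before ranking.
#' @return tibble `(pt, a, b, c, d, ror, ror_lo, ror_hi)` ranked by count.
#' @export
top_k_pts <- function(reports, k = 20, target_class = c("hexa", "penta"),
                      stratum = NULL) {
  if (k < 1) stop("top_k_pts: k must be >= 1")
  target_class <- match.arg(target_class)
  if (!is.null(stratum)) {
    strata <- stratify(reports, stratum$factor)
    reports <- strata[[as.character(stratum$level)]]
    if (is.null(reports) || !nrow(reports)) {
      warning("top_k_pts: empty stratum ", stratum$factor, " = ",
        stratum$level, call. = FALSE)
      return(tibble::tibble(pt = character(), a = integer(), b = integer(),
        c = integer(), d = integer(), ror = numeric(), ror_lo = numeric(),
        ror_hi = numeric()))
    }
  }
  if (!any(reports$vaccine_class == target_class)) {
    warning("top_k_pts: no ", target_class, " reports in stratum", call. = FALSE)
    return(tibble::tibble(pt = character(), a = integer(), b = integer(),
      c = integer(), d = integer(), ror = numeric(), ror_lo = numeric(),
      ror_hi = numeric()))
  }
  tables <- build_all_tables(reports, level = "PT", target_class = target_class)
  tables <- utils::head(tables, k)  # already ordered by descending a, then label
  stats <- ror(tables)
  tibble::tibble(pt = tables$event, a = tables$a, b = tables$b,
    c = tables$c, d = tables$d, ror = stats$ror,
    ror_lo = stats$ror_lo, ror_hi = stats$ror_hi)
}
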