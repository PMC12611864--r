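# Reading the VAERS public-extract dialect and building the analysis cohort.

#' Cohort-selection configuration
#'
#' Parameters of the cohort filter: reporting window, infant age window,
#' vaccine-name patterns for the two combination-vaccine classes, the
#' vocabulary, and the vaccination-error PT list whose error-only reports
#' are excluded.
#'
#' @param start_year,end_year inclusive reporting window (calendar years).
#' @param min_age_days,max_age_days inclusive age window; defaults 42 days
#'   (6 weeks) to 730 days (2 years).
#' @param penta_pattern,hexa_pattern regular expressions matched against
#'   `VAX_NAME`. A name matching both resolves to hexavalent (the stricter,
#'   HepB-containing pattern).
#' @param vocab vocabulary tibble; `NULL` loads the bundled toy vocabulary.
#' @param error_pts PT labels that denote vaccination errors; a report whose
#'   whole PT set falls in this list is excluded.
#' @param comparator_mode default comparator for downstream contingency
#'   tables: `"other_class"` or `"external_background"`.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(start_year = 2018, end_year = 2024,
                          min_age_days = 42, max_age_days = 730,
                          penta_pattern = "DTAP\\s*\\+\\s*IPV\\s*\\+\\s*HIB",
                          hexa_pattern = "DTAP\\s*\\+\\s*IPV\\s*\\+\\s*HEPB\\s*\\+\\s*HIB",
                          vocab = NULL,
                          error_pts = default_error_pts(),
                          comparator_mode = c("other_class", "external_background")) {
  if (start_year > end_year) stop("cohort_config: start_year must be <= end_year")
  if (min_age_days >= max_age_days) stop("cohort_config: min age must be below max age")
  structure(list(
    start_year = start_year, end_year = end_year,
    min_age_years = min_age_days / DAYS_PER_YEAR,
    max_age_years = max_age_days / DAYS_PER_YEAR,
    penta_pattern = penta_pattern, hexa_pattern = hexa_pattern,
    vocab = vocab %||% load_pt_vocab(),
    error_pts = error_pts,
    comparator_mode = match.arg(comparator_mode)
  ), class = "cohort_config")
}

read_csv_chr <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, na = character()
  )
}

require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    stop("file ", path, " is missing mandatory column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a VAERS public-extract set
#'
#' Reads and joins the three VAERS tables (DATA, VAX, SYMPTOMS), possibly
#' across several years (pass vectors of paths). `SYMPTOM1..5` columns are
#' gathered into one de-duplicated PT set per report. The result is one
#' logical row per (report, vaccine) pair; duplicate `VAERS_ID`s across
#' files are retained for the downstream de-duplication stage.
#'
#' @param data_files,vax_files,symptoms_files character vectors of CSV paths
#'   (parallel order across years).
#' @return a raw joined tibble with one row per (report, vaccine), a `pts`
#'   list-column, and a `file_order` column preserving input order.
#' @export
read_vaers_extract <- function(data_files, vax_files, symptoms_files) {
  for (p in c(data_files, vax_files, symptoms_files)) {
    if (!file.exists(p)) stop("VAERS extract file does not exist: ", p)
  }
  data_tbl <- dplyr::bind_rows(lapply(data_files, function(p) {
    tbl <- read_csv_chr(p)
    require_columns(tbl, c("VAERS_ID", "AGE_YRS", "SEX", "DIED", "L_THREAT",
      "HOSPITAL", "X_STAY", "DISABLE", "RECOVD", "NUMDAYS"), p)
    tbl
  }))
  vax_tbl <- dplyr::bind_rows(lapply(vax_files, function(p) {
    tbl <- read_csv_chr(p)
    require_columns(tbl, c("VAERS_ID", "VAX_NAME"), p)
    tbl
  }))
  sym_tbl <- dplyr::bind_rows(lapply(symptoms_files, function(p) {
    tbl <- read_csv_chr(p)
    require_columns(tbl, c("VAERS_ID", "SYMPTOM1"), p)
    tbl
  }))

  sym_cols <- intersect(paste0("SYMPTOM", 1:5), names(sym_tbl))
  pts_long <- tidyr::pivot_longer(
    sym_tbl[, c("VAERS_ID", sym_cols)],
    cols = dplyr::all_of(sym_cols), values_to = "pt"
  )
  pts_long <- pts_long[!is.na(pts_long$pt) & pts_long$pt != "", ]
  pts_by_id <- pts_long |>
    dplyr::group_by(.data$VAERS_ID) |>
    dplyr::summarise(pts = list(sort_pts(.data$pt)), .groups = "drop")

  data_tbl$file_order <- seq_len(nrow(data_tbl))
  raw <- data_tbl |>
    dplyr::left_join(vax_tbl[, c("VAERS_ID", "VAX_NAME")], by = "VAERS_ID",
      relationship = "many-to-many") |>
    dplyr::left_join(pts_by_id, by = "VAERS_ID")
  n_unparseable <- sum(!is.na(raw$AGE_YRS) & raw$AGE_YRS != "" &
    is.na(suppressWarnings(as.numeric(raw$AGE_YRS))))
  if (n_unparseable > 0) {
    message("read_vaers_extract: ", n_unparseable,
      " row(s) with unparseable AGE_YRS retained with age set to missing")
  }
  raw
}

blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)

#' Select the analysis cohort
#'
#' Applies the cohort-selection rules to a raw joined extract: (i) keep
#' reports with at least one vaccine row matching one of the two
#' combination-vaccine name patterns (names matching both resolve to
#' hexavalent); (ii) keep ages within the configured window (6 weeks to
#' 2 years by default, with a half-rounding-step tolerance because
#' `AGE_YRS` carries 2 decimals); (iii) de-duplicate by report id, keeping
#' the first occurrence in file order; (iv) exclude reports whose entire PT
#' set consists of vaccination-error terms. A one-line attrition message is
#' emitted per rule.
#'
#' @param raw joined tibble from [read_vaers_extract()].
#' @param config a [cohort_config()].
#' @return an analysis-ready report tibble (one row per retained report).
#' @export
select_cohort <- function(raw, config = cohort_config()) {
  if (!nrow(raw)) stop("select_cohort: empty raw table")
  raw$VAX_NAME <- blank_to_na(raw$VAX_NAME)
  per_vax <- tibble::tibble(
    VAERS_ID = raw$VAERS_ID,
    is_hexa = !is.na(raw$VAX_NAME) & grepl(config$hexa_pattern, raw$VAX_NAME, ignore.case = TRUE),
    is_penta = !is.na(raw$VAX_NAME) & grepl(config$penta_pattern, raw$VAX_NAME, ignore.case = TRUE)
  )
  per_vax$is_other <- !is.na(raw$VAX_NAME) & !per_vax$is_hexa & !per_vax$is_penta
  by_id <- per_vax |>
    dplyr::group_by(.data$VAERS_ID) |>
    dplyr::summarise(
      any_hexa = any(.data$is_hexa), any_penta = any(.data$is_penta & !.data$is_hexa),
      both = any(.data$is_hexa) && any(.data$is_penta & !.data$is_hexa),
      vaccine_alone = !any(.data$is_other), .groups = "drop"
    )
  n_both <- sum(by_id$both)
  if (n_both > 0) {
    message("select_cohort: ", n_both,
      " report(s) matched both name patterns; resolved to hexavalent")
  }

  first_rows <- raw[!duplicated(raw$VAERS_ID), ]
  n0 <- nrow(first_rows)
  recs <- dplyr::left_join(first_rows, by_id, by = "VAERS_ID")

  recs$vaccine_class <- ifelse(recs$any_hexa, "hexa",
    ifelse(recs$any_penta, "penta", NA_character_))
  recs <- recs[!is.na(recs$vaccine_class), ]
  n1 <- nrow(recs)

  age <- suppressWarnings(as.numeric(blank_to_na(recs$AGE_YRS)))
  if ("CAGE_YR" %in% names(recs)) {
    cage <- suppressWarnings(as.numeric(blank_to_na(recs$CAGE_YR)))
    if ("CAGE_MO" %in% names(recs)) {
      cage_mo <- suppressWarnings(as.numeric(blank_to_na(recs$CAGE_MO)))
      cage <- ifelse(is.na(cage), 0, cage) + ifelse(is.na(cage_mo), 0, cage_mo / 12)
      cage[is.na(suppressWarnings(as.numeric(blank_to_na(recs$CAGE_YR)))) &
        is.na(cage_mo)] <- NA
    }
    age <- ifelse(is.na(age), cage, age)
  }
  recs$age_years <- age
  keep_age <- !is.na(age) &
    age >= config$min_age_years - AGE_TOL &
    age <= config$max_age_years + AGE_TOL
  recs <- recs[keep_age, ]
  n2 <- nrow(recs)

  year <- if ("RECVDATE" %in% names(recs)) {
    suppressWarnings(as.integer(substr(blank_to_na(recs$RECVDATE), 1, 4)))
  } else rep(NA_integer_, nrow(recs))
  keep_year <- is.na(year) | (year >= config$start_year & year <= config$end_year)
  recs <- recs[keep_year, ]
  year <- year[keep_year]
  n3 <- nrow(recs)

  pts <- recs$pts
  pts[vapply(pts, is.null, logical(1))] <- list(character(0))
  error_only <- vapply(pts, function(p) {
    length(p) > 0 && all(p %in% config$error_pts)
  }, logical(1))
  empty <- lengths(pts) == 0
  recs <- recs[!error_only & !empty, ]
  year <- year[!error_only & !empty]
  n4 <- nrow(recs)

  message(sprintf(paste0(
    "select_cohort: %d unique reports; %d after vaccine-name match; ",
    "%d after age window; %d after report-year window; ",
    "%d after excluding error-only/empty PT sets"), n0, n1, n2, n3, n4))
  if (n4 == 0) stop("select_cohort: empty cohort after filtering")

  near_dup <- duplicated(data.frame(
    recs$vaccine_class, recs$age_years, recs$SEX,
    vapply(recs$pts, paste, character(1), collapse = "|")
  ))
  if (any(near_dup)) {
    message("select_cohort: ", sum(near_dup),
      " possible near-duplicate report(s) retained (same class/age/sex/PT set)")
  }

  yn <- function(x) !is.na(blank_to_na(x)) & blank_to_na(x) == "Y"
  recovered <- dplyr::case_match(blank_to_na(recs$RECOVD),
    "Y" ~ "yes", "N" ~ "no", "U" ~ "unknown", .default = "missing")
  onset <- suppressWarnings(as.integer(blank_to_na(recs$NUMDAYS)))
  onset[!is.na(onset) & onset < 0] <- NA_integer_

  out <- tibble::tibble(
    report_id = recs$VAERS_ID,
    vaccine_class = factor(recs$vaccine_class, levels = VACCINE_CLASSES),
    age_years = recs$age_years,
    age_group = assign_age_group(recs$age_years),
    sex = factor(dplyr::case_match(blank_to_na(recs$SEX),
      "M" ~ "male", "F" ~ "female", .default = "unknown"), levels = SEX_LEVELS),
    died = yn(recs$DIED),
    life_threatening = yn(recs$L_THREAT),
    hospitalized = yn(recs$HOSPITAL),
    prolonged_hosp = yn(recs$X_STAY),
    disabled = yn(recs$DISABLE),
    recovered = factor(recovered, levels = RECOVERED_LEVELS),
    vaccine_alone = recs$vaccine_alone,
    onset_days = onset,
    report_year = year,
    region = if ("STATE" %in% names(recs)) blank_to_na(recs$STATE) else NA_character_,
    pts = lapply(recs$pts, sort_pts)
  )
  out$serious <- out$died | out$life_threatening | out$hospitalized |
    out$prolonged_hosp | out$disabled
  out$socs <- lapply(out$pts, function(p) {
    sort_pts(suppressWarnings(map_pt_to_soc(p, config$vocab)))
  })
  out[, c("report_id", "vaccine_class", "age_years", "age_group", "sex",
    "died", "life_threatening", "hospitalized", "prolonged_hosp", "disabled",
    "recovered", "serious", "vaccine_alone", "onset_days", "report_year",
    "region", "pts", "socs")]
}

#' Summarize the cohort as a characteristics table
#'
#' Produces the published-style per-class summary: N, counts and percentages
#' (one decimal, class N as denominator) for sex, the serious composite,
#' vaccine-alone status, each seriousness flag and recovery outcome;
#' per-year report counts; a time-to-onset histogram with bins 0, 1, 2-7,
#' 8-30, >30 days and missing; and per-region counts.
#'
#' @param reports analysis-ready report tibble.
#' @param digits decimals for percentages (default 1, half-up rounding).
#' @return list with tibbles `characteristics`, `by_year`, `onset_bins`,
#'   `by_region`.
#' @export
summarize_cohort <- function(reports, digits = 1) {
  if (!nrow(reports)) stop("summarize_cohort: empty cohort")
  class_n <- table(reports$vaccine_class)

  block <- function(characteristic, values, levels) {
    do.call(rbind, lapply(VACCINE_CLASSES, function(cl) {
      v <- factor(values[reports$vaccine_class == cl], levels = levels)
      cnt <- table(v)
      tibble::tibble(
        characteristic = characteristic,
        level = levels,
        vaccine_class = cl,
        n = as.integer(cnt),
        pct = round_half_up(100 * as.integer(cnt) / class_n[[cl]], digits)
      )
    }))
  }
  yn_lvls <- c("no", "yes")
  to_yn <- function(x) ifelse(x, "yes", "no")
  characteristics <- dplyr::bind_rows(
    tibble::tibble(
      characteristic = "n", level = "total",
      vaccine_class = VACCINE_CLASSES,
      n = as.integer(class_n[VACCINE_CLASSES]), pct = 100
    ),
    block("sex", as.character(reports$sex), SEX_LEVELS),
    block("serious", to_yn(reports$serious), yn_lvls),
    block("vaccine_alone", to_yn(reports$vaccine_alone), yn_lvls),
    block("died", to_yn(reports$died), yn_lvls),
    block("life_threatening", to_yn(reports$life_threatening), yn_lvls),
    block("hospitalized", to_yn(reports$hospitalized), yn_lvls),
    block("prolonged_hosp", to_yn(reports$prolonged_hosp), yn_lvls),
    block("disabled", to_yn(reports$disabled), yn_lvls),
    block("recovered", as.character(reports$recovered), RECOVERED_LEVELS)
  )

  by_year <- reports |>
    dplyr::count(.data$vaccine_class, year = .data$report_year, name = "n") |>
    tibble::as_tibble()

  onset_bin <- function(d) {
    ifelse(is.na(d), "missing",
      ifelse(d == 0, "0",
        ifelse(d == 1, "1",
          ifelse(d <= 7, "2-7",
            ifelse(d <= 30, "8-30", ">30")))))
  }
  bins <- c("0", "1", "2-7", "8-30", ">30", "missing")
  onset_bins <- reports |>
    dplyr::mutate(bin = factor(onset_bin(.data$onset_days), levels = bins)) |>
    dplyr::count(.data$vaccine_class, .data$bin, .drop = FALSE, name = "n") |>
    tibble::as_tibble()

  by_region <- reports |>
    dplyr::count(.data$vaccine_class, .data$region, name = "n") |>
    dplyr::arrange(.data$vaccine_class, dplyr::desc(.data$n)) |>
    tibble::as_tibble()

  list(characteristics = tibble::as_tibble(characteristics),
    by_year = by_year, onset_bins = onset_bins, by_region = by_region)
}
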