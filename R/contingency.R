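# 2x2 contingency tables underlying the disproportionality statistics.
# Counting is report-level: a report mentioning an event through one or
# more PTs contributes 1 to cell a, never more.

event_sets <- function(reports, level = c("PT", "SOC")) {
  level <- match.arg(level)
  if (level == "PT") reports$pts else reports$socs
}

#' Build one 2x2 contingency table
#'
#' Cell `a` counts target-class reports mentioning the event, `b` those not
#' mentioning it; `c`/`d` are the comparator's counts. The comparator is
#' either the other vaccine class's cohort reports (`"other_class"`, the
#' default) or a user-supplied external background (`"external_background"`,
#' via `background = c(c = ..., d = ...)`), as classical spontaneous-report
#' practice screens against all-other-reports.
#'
#' @param reports analysis-ready report tibble.
#' @param event event label (a PT or a SOC).
#' @param level `"PT"` or `"SOC"`.
#' @param target_class `"penta"` or `"hexa"`.
#' @param comparator_mode `"other_class"` or `"external_background"`.
#' @param background named vector `c(c = ..., d = ...)` of background counts
#'   when `comparator_mode = "external_background"`.
#' @return a one-row tibble with `event`, `level`, `target_class`, `a`, `b`,
#'   `c`, `d`.
#' @export
build_table <- function(reports, event, level = c("PT", "SOC"),
                        target_class = c("hexa", "penta"),
                        comparator_mode = c("other_class", "external_background"),
                        background = NULL) {
  level <- match.arg(level)
  target_class <- match.arg(target_class)
  comparator_mode <- match.arg(comparator_mode)
  sets <- event_sets(reports, level)
  in_target <- reports$vaccine_class == target_class
  mentions <- vapply(sets, function(s) event %in% s, logical(1))

  a <- sum(in_target & mentions)
  b <- sum(in_target & !mentions)
  if (comparator_mode == "other_class") {
    c_ <- sum(!in_target & mentions)
    d_ <- sum(!in_target & !mentions)
    if (c_ + d_ == 0) stop("build_table: comparator class has no reports")
  } else {
    if (is.null(background) || !all(c("c", "d") %in% names(background))) {
      stop("build_table: external_background mode needs background = c(c = ..., d = ...)")
    }
    c_ <- background[["c"]]
    d_ <- background[["d"]]
    if (c_ + d_ == 0) stop("build_table: empty external background")
  }
  tibble::tibble(event = event, level = level, target_class = target_class,
    a = a, b = b, c = c_, d = d_)
}

#' Build contingency tables for all observed events
#'
#' One table per distinct event label observed in the target class (so
#' `a >= 1` for every table), ordered by descending `a` then event label.
#' Because reports carry several PTs, the `a` cells across PT tables may sum
#' to more than the target class size.
#'
#' @inheritParams build_table
#' @return tibble of tables, one row per event.
#' @export
build_all_tables <- function(reports, level = c("PT", "SOC"),
                             target_class = c("hexa", "penta"),
                             comparator_mode = c("other_class", "external_background"),
                             background = NULL) {
  level <- match.arg(level)
  target_class <- match.arg(target_class)
  comparator_mode <- match.arg(comparator_mode)
  sets <- event_sets(reports, level)
  in_target <- reports$vaccine_class == target_class

  count_events <- function(idx) {
    if (!any(idx)) return(integer(0))
    tab <- table(unlist(sets[idx], use.names = FALSE))
    stats::setNames(as.integer(tab), names(tab))
  }
  a_counts <- count_events(in_target)
  if (!length(a_counts)) {
    stop("build_all_tables: target class has no reports or no events")
  }
  n_target <- sum(in_target)
  events <- names(a_counts)

  if (comparator_mode == "other_class") {
    n_comp <- sum(!in_target)
    if (n_comp == 0) stop("build_all_tables: comparator class has no reports")
    c_counts <- count_events(!in_target)
    c_vec <- ifelse(events %in% names(c_counts), c_counts[events], 0L)
    out <- tibble::tibble(
      event = events, level = level, target_class = target_class,
      a = unname(a_counts), b = n_target - unname(a_counts),
      c = as.integer(unname(c_vec)), d = n_comp - as.integer(unname(c_vec))
    )
  } else {
    if (is.null(background) || !is.data.frame(background) ||
        !all(c("event", "c", "d") %in% names(background))) {
      stop("build_all_tables: external_background mode needs a background data ",
        "frame with columns event, c, d")
    }
    idx <- match(events, background$event)
    if (anyNA(idx)) {
      stop("build_all_tables: background lacks counts for event(s): ",
        paste(utils::head(events[is.na(idx)], 5), collapse = ", "))
    }
    out <- tibble::tibble(
      event = events, level = level, target_class = target_class,
      a = unname(a_counts), b = n_target - unname(a_counts),
      c = as.integer(background$c[idx]), d = as.integer(background$d[idx])
    )
  }
  out[order(-out$a, out$event, method = "radix"), ]
}
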