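# Frequentist and Bayesian disproportionality statistics on 2x2 report
# tables, with the signal thresholds used throughout the analysis:
#   ROR >= 3 with 95% CI lower bound > 1
#   PRR >= 2 with event count a >= 3
#   BCPNN IC025 > 0
#   MGPS EB05 > 2
# and the consensus rule: an event signals when at least two of the four
# methods flag it.

# Haldane-Anscombe continuity correction: +0.5 on all four cells, applied
# only when the table contains a zero cell.
corrected_cells <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k)
}

#' Reporting odds ratio
#'
#' Classical ROR `(a d)/(b c)` with a log-normal Wald 95% interval,
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Cells receive the
#' Haldane-Anscombe +0.5 correction when (and only when) the table contains
#' a zero. Signal flag: ROR >= 3 and CI lower bound > 1. Vectorized over
#' the rows of `tables`.
#'
#' @param tables tibble with integer columns `a`, `b`, `c`, `d` (from
#'   [build_table()] / [build_all_tables()]).
#' @return tibble with `ror`, `ror_lo`, `ror_hi`, `ror_flag`.
#' @export
ror <- function(tables) {
  cc <- corrected_cells(tables$a, tables$b, tables$c, tables$d)
  est <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  lo <- exp(log(est) - 1.96 * se)
  hi <- exp(log(est) + 1.96 * se)
  tibble::tibble(ror = est, ror_lo = lo, ror_hi = hi,
    ror_flag = est >= 3 & lo > 1)
}

#' Proportional reporting ratio
#'
#' PRR `[a/(a+b)] / [c/(c+d)]`, with the same zero-cell correction rule as
#' [ror()]. The Yates-corrected Pearson chi-square of the uncorrected table
#' is reported for reference. Signal flag: PRR >= 2 and target event count
#' `a >= 3` (the "N >= 3" of the usual PRR criterion read as the target
#' cell count).
#'
#' @inheritParams ror
#' @return tibble with `prr`, `chi2`, `prr_flag`.
#' @export
prr <- function(tables) {
  cc <- corrected_cells(tables$a, tables$b, tables$c, tables$d)
  est <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  n <- a + b + c + d
  num <- n * (pmax(abs(a * d - b * c) - n / 2, 0))^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(prr = est, chi2 = chi2, prr_flag = est >= 2 & a >= 3)
}

#' BCPNN information component with lower credible bound
#'
#' Shrunk observed-to-expected information component in bits:
#' `IC = log2((a + 0.5) / (E + 0.5))` with expected count
#' `E = (a+b)(a+c)/N` under row-column independence. The posterior of the
#' shrunk reporting ratio is `Gamma(shape = a + 0.5, rate = E + 0.5)`, and
#' `IC025 = log2` of its 2.5% quantile. Signal flag: IC025 > 0.
#'
#' @inheritParams ror
#' @param stratified_e optional numeric vector of externally computed
#'   expected counts (e.g. summed over strata), overriding the
#'   unstratified product.
#' @return tibble with `expected`, `ic`, `ic025`, `bcpnn_flag`.
#' @export
bcpnn_ic <- function(tables, stratified_e = NULL) {
  e <- stratified_e %||% expected_count(tables)
  a <- tables$a
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, rate = e + 0.5))
  tibble::tibble(expected = e, ic = ic, ic025 = ic025, bcpnn_flag = ic025 > 0)
}

#' Expected event count under independence
#'
#' `E = (a+b)(a+c)/N`: the count expected for the target class if the event
#' were reported at the pooled rate. With `by`, a stratified version
#' summing the per-stratum products is available for confounding control.
#'
#' @inheritParams ror
#' @return numeric vector of expected counts.
#' @export
expected_count <- function(tables) {
  n <- tables$a + tables$b + tables$c + tables$d
  (tables$a + tables$b) * (tables$a + tables$c) / n
}

#' Annotate per-method flags with the consensus signal
#'
#' The consensus rule declares a signal when at least two of the four
#' per-method flags are true. Results are ordered by descending consensus,
#' then descending target event count `a`, then event label.
#'
#' @param results tibble carrying logical columns `ror_flag`, `prr_flag`,
#'   `bcpnn_flag`, `mgps_flag` (NA flags count as not flagged) and `a`.
#' @return the tibble with `n_flags` and `consensus` columns, reordered.
#' @export
flag_signals <- function(results) {
  flags <- cbind(results$ror_flag, results$prr_flag,
    results$bcpnn_flag, results$mgps_flag)
  flags[is.na(flags)] <- FALSE
  results$n_flags <- as.integer(rowSums(flags))
  results$consensus <- results$n_flags >= 2
  key_event <- if ("event" %in% names(results)) results$event else seq_len(nrow(results))
  results[order(-results$consensus, -results$a, key_event, method = "radix"), ]
}

#' Compute all four disproportionality statistics per event
#'
#' Runs [ror()], [prr()], [bcpnn_ic()] and [mgps_scores()] over a table
#' collection and applies the consensus rule. The MGPS prior is fitted on
#' the same collection unless supplied; when the collection has fewer than
#' 20 tables and no prior is given, MGPS columns are NA and its flag counts
#' as false (with a message), since the five mixture hyperparameters are
#' not identifiable from so few events.
#'
#' @inheritParams ror
#' @param prior an [fit_mgps_prior()] result, or `NULL` to fit from
#'   `tables`.
#' @param stratified_e optional expected-count override passed to the
#'   Bayesian statistics.
#' @return a signal-result tibble: the table cells, `expected`, all four
#'   statistics with their interval bounds, per-method flags, `n_flags`
#'   and `consensus`.
#' @export
compute_signals <- function(tables, prior = NULL, stratified_e = NULL) {
  res <- dplyr::bind_cols(
    tables,
    ror(tables),
    prr(tables),
    bcpnn_ic(tables, stratified_e = stratified_e)
  )
  if (is.null(prior) && nrow(tables) >= 20) {
    prior <- fit_mgps_prior(tables, stratified_e = stratified_e)
  }
  if (is.null(prior)) {
    message("compute_signals: fewer than 20 tables and no prior supplied; ",
      "MGPS scores reported as NA")
    res$ebgm <- NA_real_
    res$eb05 <- NA_real_
    res$mgps_flag <- NA
  } else {
    res <- dplyr::bind_cols(res,
      mgps_scores(tables, prior, stratified_e = stratified_e))
  }
  flag_signals(res)
}
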