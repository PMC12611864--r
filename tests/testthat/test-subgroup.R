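# Stratified analyses and the ranked top-K PT tables.

test_that("strata partition the cohort and keep missing levels", {
  g <- generate_reports(sim_config(n_penta = 400, n_hexa = 300,
    pt_vocab = tiny_vocab(), seed = 17))
  reports <- g$reports
  for (f in c("age_group", "sex", "serious")) {
    strata <- stratify(reports, f)
    expect_equal(sum(vapply(strata, nrow, integer(1))), nrow(reports))
    expect_false(anyDuplicated(unlist(lapply(strata, function(s) s$report_id))) > 0)
  }
  # generator bookkeeping matches the age-group split sizes
  strata <- stratify(reports, "age_group")
  truth_sizes <- g$truth$group_sizes
  for (grp in names(strata)) {
    expect_equal(nrow(strata[[grp]]),
      sum(truth_sizes$n[truth_sizes$age_group == grp]))
  }
  # unknown sex forms its own stratum, never dropped
  sex_strata <- stratify(reports, "sex")
  expect_equal(sum(reports$sex == "unknown"), nrow(sex_strata[["unknown"]]))
})

test_that("stratified event counts sum to the unstratified counts", {
  g <- generate_reports(sim_config(n_penta = 400, n_hexa = 300,
    pt_vocab = tiny_vocab(), seed = 18))
  whole <- build_all_tables(g$reports, level = "PT", target_class = "hexa")
  strata <- stratify(g$reports, "age_group")
  summed <- Reduce(`+`, lapply(strata, function(s) {
    a <- integer(nrow(whole))
    sets <- s$pts[s$vaccine_class == "hexa"]
    for (i in seq_along(whole$event)) {
      a[i] <- sum(vapply(sets, function(x) whole$event[i] %in% x, logical(1)))
    }
    a
  }))
  expect_equal(summed, whole$a)
})

test_that("top-K ranking is count-descending with alphabetical tie-break", {
  reports <- dplyr::bind_rows(
    make_reports("hexa", list("Pyrexia", c("Pyrexia", "Apnoea"), "Apnoea",
      "Crying", "Rash")),
    make_reports("penta", list("Pyrexia", "Crying", "Rash", "Vomiting"))
  )
  full <- top_k_pts(reports, k = 10, target_class = "hexa")
  # Apnoea and Pyrexia tie at 2; alphabetical order breaks the tie
  expect_identical(full$pt[1:2], c("Apnoea", "Pyrexia"))
  expect_equal(full$a[1:2], c(2L, 2L))
  # k beyond the distinct-PT count returns the full list, no padding
  expect_equal(nrow(full), 4)
  head1 <- top_k_pts(reports, k = 1, target_class = "hexa")
  expect_identical(head1$pt, "Apnoea")
  # brute-force sort oracle on a generated stratum
  g <- generate_reports(sim_config(n_penta = 300, n_hexa = 300,
    pt_vocab = tiny_vocab(), seed = 19))
  tk <- top_k_pts(g$reports, k = 100, target_class = "hexa",
    stratum = list(factor = "age_group", level = "G1"))
  sub <- g$reports[g$reports$age_group == "G1", ]
  counts <- table(unlist(sub$pts[sub$vaccine_class == "hexa"]))
  oracle <- counts[order(-as.integer(counts), names(counts), method = "radix")]
  expect_identical(tk$pt, names(oracle))
  expect_equal(tk$a, as.integer(oracle))
  # RORs computed within the same stratum
  t1 <- build_table(sub, tk$pt[1], level = "PT", target_class = "hexa")
  expect_equal(tk$ror[1], ror(t1)$ror)
})

test_that("empty strata warn and return empty results", {
  reports <- make_reports("hexa", list("Pyrexia", "Apnoea"), sex = "male")
  expect_warning(tk <- top_k_pts(reports, k = 5, target_class = "hexa",
    stratum = list(factor = "sex", level = "female")), "empty stratum")
  expect_equal(nrow(tk), 0)
  expect_warning(top_k_pts(reports, k = 5, target_class = "penta"), "no penta")
})

test_that("per-stratum signal analysis reuses the full machinery", {
  g <- generate_reports(sim_config(n_penta = 600, n_hexa = 600,
    pt_vocab = tiny_vocab(), seed = 23))
  prior <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  res <- subgroup_signals(g$reports, factor = "sex", level = "PT",
    target_class = "hexa", prior = prior)
  expect_true(all(c("stratum", "event", "ror", "consensus") %in% names(res)))
  expect_true(all(res$stratum %in% c("male", "female", "unknown")))
  # each stratum's rows equal a direct per-stratum computation
  strata <- stratify(g$reports, "sex")
  direct <- compute_signals(build_all_tables(strata[["male"]], level = "PT",
    target_class = "hexa"), prior = prior)
  got <- res[res$stratum == "male", names(direct)]
  expect_equal(as.data.frame(got), as.data.frame(direct), ignore_attr = TRUE)
})
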