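# VAERS-dialect ingestion and cohort selection.

test_that("symptom columns gather into de-duplicated PT sets and blanks survive", {
  d <- withr::local_tempdir()
  paths <- write_raw_dialect(d,
    dplyr::bind_rows(
      data_row("1001"),
      data_row("1002", age = "")  # blank age retained, excluded later
    ),
    dplyr::bind_rows(vax_row("1001"), vax_row("1002")),
    dplyr::bind_rows(
      sym_row("1001", c("Pyrexia", "Crying", "Seizure", "Apnoea", "Vomiting")),
      sym_row("1001", c("Rash", "Pyrexia", "Somnolence")),  # repeated PT
      sym_row("1002", "Pyrexia")
    )
  )
  raw <- read_vaers_extract(paths[["data"]], paths[["vax"]], paths[["symptoms"]])
  pts_1001 <- raw$pts[raw$VAERS_ID == "1001"][[1]]
  expect_length(pts_1001, 7)
  expect_identical(pts_1001, sort(unique(pts_1001)))
  expect_true("1002" %in% raw$VAERS_ID)  # retained despite blank age
})

test_that("missing mandatory columns fail loudly, naming file and column", {
  d <- withr::local_tempdir()
  bad <- data_row("1")
  bad$AGE_YRS <- NULL
  paths <- write_raw_dialect(d, bad, vax_row("1"), sym_row("1", "Pyrexia"))
  expect_error(
    read_vaers_extract(paths[["data"]], paths[["vax"]], paths[["symptoms"]]),
    "AGE_YRS")
})

test_that("cohort selection applies the four rules as a brute-force recount", {
  # 6 reports: one duplicate id, one error-only PT set, one aged 3 years,
  # and 3 clean -> 3 retained
  d <- withr::local_tempdir()
  paths <- write_raw_dialect(d,
    dplyr::bind_rows(
      data_row("1"),                      # clean penta
      data_row("1"),                      # duplicate id
      data_row("2", age = "3.00"),        # too old
      data_row("3"),                      # error-only PT set
      data_row("4", sex = "F"),           # clean hexa
      data_row("5", sex = "")             # clean penta, unknown sex
    ),
    dplyr::bind_rows(
      vax_row("1"), vax_row("1"), vax_row("2"), vax_row("3"),
      vax_row("4", HEXA_NAME), vax_row("5")
    ),
    dplyr::bind_rows(
      sym_row("1", "Pyrexia"), sym_row("2", "Pyrexia"),
      sym_row("3", c("Incorrect dose administered", "Wrong product administered")),
      sym_row("4", "Seizure"), sym_row("5", "Rash")
    )
  )
  raw <- read_vaers_extract(paths[["data"]], paths[["vax"]], paths[["symptoms"]])
  coh <- suppressMessages(select_cohort(raw))
  expect_setequal(coh$report_id, c("1", "4", "5"))
  expect_false(anyDuplicated(coh$report_id) > 0)
  expect_identical(as.character(coh$vaccine_class[coh$report_id == "4"]), "hexa")
  expect_identical(as.character(coh$sex[coh$report_id == "5"]), "unknown")
})

test_that("co-administration and boundary ages resolve per the documented rules", {
  d <- withr::local_tempdir()
  paths <- write_raw_dialect(d,
    dplyr::bind_rows(
      data_row("10", age = "0.11"),  # exactly 6 weeks, 2-dp storage
      data_row("11", age = "2.00")   # exactly 2 years
    ),
    dplyr::bind_rows(
      vax_row("10", HEXA_NAME),
      vax_row("10", "INFLUENZA (FLUZONE)", type = "FLU3"),
      vax_row("11")
    ),
    dplyr::bind_rows(sym_row("10", "Apnoea"), sym_row("11", "Pyrexia"))
  )
  coh <- suppressMessages(select_cohort(
    read_vaers_extract(paths[["data"]], paths[["vax"]], paths[["symptoms"]])))
  expect_setequal(coh$report_id, c("10", "11"))
  expect_identical(as.character(coh$age_group[coh$report_id == "10"]), "G1")
  expect_false(coh$vaccine_alone[coh$report_id == "10"])
  expect_true(coh$vaccine_alone[coh$report_id == "11"])
  expect_identical(as.character(coh$age_group[coh$report_id == "11"]), "G3")
})

test_that("write/read round trip is the identity on a generated cohort", {
  g <- generate_reports(sim_config(n_penta = 300, n_hexa = 200, seed = 99))
  d <- withr::local_tempdir()
  paths <- write_vaers_dialect(g$reports, d)
  coh <- suppressMessages(select_cohort(
    read_vaers_extract(paths[["data"]], paths[["vax"]], paths[["symptoms"]])))
  a <- g$reports[order(g$reports$report_id), ]
  b <- coh[order(coh$report_id), names(a)]
  expect_equal(nrow(b), nrow(a))
  for (col in names(a)) {
    expect_equal(b[[col]], a[[col]], info = col, ignore_attr = TRUE)
  }
  # selection is idempotent: re-serializing the selected cohort and
  # selecting again changes nothing
  d2 <- withr::local_tempdir()
  paths2 <- write_vaers_dialect(coh, d2)
  coh2 <- suppressMessages(select_cohort(
    read_vaers_extract(paths2[["data"]], paths2[["vax"]], paths2[["symptoms"]])))
  expect_equal(coh2[order(coh2$report_id), names(a)], b, ignore_attr = TRUE)
})

test_that("cohort summary matches published percentages and partitions class N", {
  fx <- table1_fixture()
  s <- summarize_cohort(fx)
  ch <- s$characteristics
  pick <- function(char, lvl, cl) {
    ch[ch$characteristic == char & ch$level == lvl & ch$vaccine_class == cl, ]
  }
  expect_equal(pick("serious", "yes", "penta")$pct, 13.5)
  expect_equal(pick("serious", "yes", "hexa")$pct, 38.3)
  expect_equal(pick("vaccine_alone", "yes", "hexa")$pct, 12.0)
  expect_equal(pick("vaccine_alone", "yes", "penta")$pct, 32.0)
  expect_equal(pick("hospitalized", "yes", "hexa")$pct, 34.0)
  expect_equal(pick("died", "yes", "hexa")$pct, 2.3)
  expect_equal(pick("recovered", "yes", "penta")$n, 1203L)

  # every categorical block sums to class N
  n_by_class <- c(penta = 3259L, hexa = 1720L)
  for (char in setdiff(unique(ch$characteristic), "n")) {
    for (cl in names(n_by_class)) {
      block <- ch[ch$characteristic == char & ch$vaccine_class == cl, ]
      expect_identical(sum(block$n), n_by_class[[cl]])
    }
  }
  # onset bins partition too
  for (cl in names(n_by_class)) {
    expect_identical(sum(s$onset_bins$n[s$onset_bins$vaccine_class == cl]),
      n_by_class[[cl]])
  }
})

test_that("single-report cohorts yield only 0/100 percentages", {
  rec <- make_reports("penta", list("Pyrexia"))
  s <- summarize_cohort(rec)
  pcts <- s$characteristics$pct[s$characteristics$vaccine_class == "penta"]
  expect_true(all(pcts %in% c(0, 100)))
})
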