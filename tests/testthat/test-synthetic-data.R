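# Synthetic-report generator: determinism, planted-signal structure,
# VAERS-dialect serialization, and the deterministic published-summary
# fixture.

test_that("identical config and seed give identical cohorts, different seeds differ", {
  cfg <- sim_config(n_penta = 300, n_hexa = 200, pt_vocab = tiny_vocab(), seed = 11)
  g1 <- generate_reports(cfg)
  g2 <- generate_reports(cfg)
  expect_identical(g1$reports, g2$reports)
  expect_identical(g1$truth$expected_counts, g2$truth$expected_counts)
  g3 <- generate_reports(sim_config(n_penta = 300, n_hexa = 200,
    pt_vocab = tiny_vocab(), seed = 12))
  expect_false(identical(g1$reports$pts, g3$reports$pts))
})

test_that("degenerate class counts and config validation behave as contracted", {
  g <- generate_reports(sim_config(n_penta = 0, n_hexa = 50,
    pt_vocab = tiny_vocab(), seed = 2))
  expect_equal(nrow(g$reports), 50)
  expect_true(all(g$reports$vaccine_class == "hexa"))

  expect_error(sim_config(n_penta = -1), "n_penta")
  expect_error(sim_config(p_female = 1.2), "probabilities")
  expect_error(
    sim_config(age_dist = list(penta = c(0.5, 0.4, 0.2), hexa = c(0.5, 0.3, 0.2))),
    "age_dist")
  expect_error(
    sim_config(planted_rr = data.frame(pt = "NotAPT", vaccine_class = "hexa", rr = 2)),
    "planted_rr")
})

test_that("per-PT reporting proportions track baselines under a null config", {
  cfg <- sim_config(n_penta = 10000, n_hexa = 10000, p_female = 0.5, seed = 41)
  g <- generate_reports(cfg)
  vocab <- cfg$pt_vocab
  ok <- 0L
  total <- 0L
  for (cl in c("penta", "hexa")) {
    sub <- g$reports$pts[g$reports$vaccine_class == cl]
    n <- length(sub)
    counts <- table(unlist(sub))
    for (i in seq_len(nrow(vocab))) {
      p <- vocab$baseline[i]
      cnt <- counts[vocab$pt[i]]
      phat <- (if (is.na(cnt)) 0L else as.integer(cnt)) / n
      se <- sqrt(p * (1 - p) / n)
      total <- total + 1L
      if (abs(phat - p) <= 3 * se) ok <- ok + 1L
    }
  }
  # the benign fallback PT intentionally exceeds its baseline; >= 95% of
  # PT-by-class proportions must still sit within 3 binomial SE
  expect_gte(ok / total, 0.95)
})

test_that("planted relative rates raise counts multiplicatively and monotonically", {
  rr2 <- data.frame(pt = "Apnoea", vaccine_class = "hexa", rr = 2)
  rr4 <- data.frame(pt = "Apnoea", vaccine_class = "hexa", rr = 4)
  cfg2 <- sim_config(n_penta = 0, n_hexa = 4000, pt_vocab = tiny_vocab(),
    planted_rr = rr2, seed = 5)
  cfg4 <- sim_config(n_penta = 0, n_hexa = 4000, pt_vocab = tiny_vocab(),
    planted_rr = rr4, seed = 5)
  e2 <- generate_reports(cfg2)$truth$expected_counts
  e4 <- generate_reports(cfg4)$truth$expected_counts
  pick <- function(e) e$expected_count[e$pt == "Apnoea" & e$vaccine_class == "hexa"]
  expect_equal(pick(e4), 2 * pick(e2))
  expect_gt(pick(e2), 0)
  # unplanted PTs unaffected
  other2 <- e2[e2$pt != "Apnoea", ]
  other4 <- e4[e4$pt != "Apnoea", ]
  expect_equal(other2$expected_count, other4$expected_count)
})

test_that("rate multipliers pushing probability past 1 clamp with a warning", {
  rr <- data.frame(pt = "Pyrexia", vaccine_class = "hexa", rr = 10)
  cfg <- sim_config(n_penta = 0, n_hexa = 100, pt_vocab = tiny_vocab(),
    planted_rr = rr, seed = 6)
  expect_warning(g <- generate_reports(cfg), "clamped")
  e <- g$truth$expected_counts
  expect_equal(e$expected_count[e$pt == "Pyrexia" & e$vaccine_class == "hexa"], 100)
})

test_that("symptom serialization uses five columns with overflow rows", {
  vocab <- load_pt_vocab()
  many_pts <- sort(vocab$pt[!vocab$pt %in% default_error_pts()][1:7])
  rec <- make_reports("hexa", list(many_pts), vocab = vocab)
  d <- withr::local_tempdir()
  paths <- write_vaers_dialect(rec, d)
  sym <- readr::read_csv(paths[["symptoms"]], show_col_types = FALSE, na = character())
  expect_equal(nrow(sym), 2)
  filled <- sum(unlist(sym[paste0("SYMPTOM", 1:5)]) != "")
  expect_equal(filled, 7)
})

test_that("co-administered reports produce multiple VAX rows per id", {
  rec <- make_reports("hexa", list("Pyrexia"), vaccine_alone = FALSE)
  d <- withr::local_tempdir()
  paths <- write_vaers_dialect(rec, d)
  vax <- readr::read_csv(paths[["vax"]], show_col_types = FALSE)
  expect_gte(sum(vax$VAERS_ID == rec$report_id[1]), 2)
})

test_that("writer rejects empty input and unwritable destinations", {
  expect_error(write_vaers_dialect(make_reports("penta", list()), tempdir()),
    "non-empty")
  rec <- make_reports("penta", list("Pyrexia"))
  expect_error(write_vaers_dialect(rec, "/proc/nope/denied"), "nope")
})

test_that("summary fixture reproduces every published margin exactly", {
  fx <- table1_fixture()
  n <- table(fx$vaccine_class)
  expect_identical(as.integer(n[["penta"]]), 3259L)
  expect_identical(as.integer(n[["hexa"]]), 1720L)

  margins <- list(
    penta = list(sex = c(male = 1588L, female = 1483L, unknown = 188L),
      serious = 440L, vaccine_alone = 1044L, died = 70L,
      life_threatening = 48L, hospitalized = 330L, prolonged_hosp = 9L,
      disabled = 61L,
      recovered = c(yes = 1203L, no = 444L, unknown = 1328L, missing = 284L)),
    hexa = list(sex = c(male = 848L, female = 753L, unknown = 119L),
      serious = 658L, vaccine_alone = 206L, died = 39L,
      life_threatening = 88L, hospitalized = 585L, prolonged_hosp = 12L,
      disabled = 32L,
      recovered = c(yes = 904L, no = 362L, unknown = 389L, missing = 65L))
  )
  for (cl in names(margins)) {
    sub <- fx[fx$vaccine_class == cl, ]
    m <- margins[[cl]]
    expect_identical(as.integer(table(sub$sex)[names(m$sex)]), unname(m$sex))
    expect_identical(sum(sub$serious), m$serious)
    expect_identical(sum(sub$vaccine_alone), m$vaccine_alone)
    for (flag in c("died", "life_threatening", "hospitalized",
      "prolonged_hosp", "disabled")) {
      expect_identical(sum(sub[[flag]]), m[[flag]])
    }
    expect_identical(as.integer(table(sub$recovered)[names(m$recovered)]),
      unname(m$recovered))
  }
  # derived-seriousness invariant holds record-wise
  expect_identical(fx$serious, fx$died | fx$life_threatening |
    fx$hospitalized | fx$prolonged_hosp | fx$disabled)
  # deterministic
  expect_identical(table1_fixture(), fx)
})
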