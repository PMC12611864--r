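# Shared fixtures: compact vocabularies and raw VAERS-dialect builders used
# across the module tests. Everything is generated in code.

# A small vocabulary for tests that do not need the full bundled one.
tiny_vocab <- function() {
  tibble::tibble(
    pt = c("Pyrexia", "Crying", "Seizure", "Apnoea", "Vomiting", "Rash",
      "Cyanosis", "Somnolence"),
    soc = c("General disorders and administration site conditions",
      "General disorders and administration site conditions",
      "Nervous system disorders",
      "Respiratory thoracic and mediastinal disorders",
      "Gastrointestinal disorders",
      "Skin and subcutaneous tissue disorders",
      "Cardiac disorders",
      "Nervous system disorders"),
    baseline = c(0.30, 0.15, 0.05, 0.04, 0.10, 0.08, 0.03, 0.06)
  )
}

# Minimal analysis-ready report tibble built from per-report arguments.
make_reports <- function(class, pts, vocab = tiny_vocab(),
                         sex = "male", age_group = "G1", died = FALSE,
                         vaccine_alone = TRUE, serious_extra = FALSE) {
  n <- length(pts)
  recycle <- function(x) rep_len(x, n)
  ag <- recycle(age_group)
  age <- c(G1 = 0.2, G2 = 0.5, G3 = 1.0)[ag]
  tibble::tibble(
    report_id = sprintf("T%04d", seq_len(n)),
    vaccine_class = factor(recycle(class), levels = c("penta", "hexa")),
    age_years = unname(age),
    age_group = factor(ag, levels = c("G1", "G2", "G3")),
    sex = factor(recycle(sex), levels = c("male", "female", "unknown")),
    died = recycle(died),
    life_threatening = recycle(serious_extra),
    hospitalized = FALSE, prolonged_hosp = FALSE, disabled = FALSE,
    recovered = factor("unknown", levels = c("yes", "no", "unknown", "missing")),
    serious = recycle(died) | recycle(serious_extra),
    vaccine_alone = recycle(vaccine_alone),
    onset_days = 1L, report_year = 2020L, region = "TX",
    pts = lapply(pts, function(p) sort(unique(p))),
    socs = lapply(pts, function(p) sort(unique(map_pt_to_soc(sort(unique(p)), vocab))))
  )
}

# Write a raw VAERS-dialect triple from explicit row lists; returns paths.
write_raw_dialect <- function(dir, data_rows, vax_rows, sym_rows) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    data = file.path(dir, "VAERSDATA.csv"),
    vax = file.path(dir, "VAERSVAX.csv"),
    symptoms = file.path(dir, "VAERSSYMPTOMS.csv")
  )
  readr::write_csv(data_rows, paths[["data"]], na = "")
  readr::write_csv(vax_rows, paths[["vax"]], na = "")
  readr::write_csv(sym_rows, paths[["symptoms"]], na = "")
  paths
}

data_row <- function(id, age = "0.25", sex = "M", died = "", l_threat = "",
                     hospital = "", x_stay = "", disable = "", recovd = "U",
                     numdays = "1", recvdate = "2020-07-01", state = "TX") {
  tibble::tibble(VAERS_ID = id, RECVDATE = recvdate, STATE = state,
    AGE_YRS = age, SEX = sex, DIED = died, L_THREAT = l_threat,
    HOSPITAL = hospital, X_STAY = x_stay, DISABLE = disable,
    RECOVD = recovd, NUMDAYS = numdays)
}

PENTA_NAME <- "DTAP + IPV + HIB (PENTACEL)"
HEXA_NAME <- "DTAP + IPV + HEPB + HIB (VAXELIS)"

vax_row <- function(id, name = PENTA_NAME, type = "DTAPIPVHIB") {
  tibble::tibble(VAERS_ID = id, VAX_TYPE = type, VAX_NAME = name)
}

sym_row <- function(id, pts) {
  padded <- c(pts, rep("", 5 - length(pts)))
  out <- tibble::as_tibble(as.list(stats::setNames(padded, paste0("SYMPTOM", 1:5))))
  dplyr::bind_cols(tibble::tibble(VAERS_ID = id), out)
}

# Independent bisection quantile oracle for a two-component gamma mixture.
bisect_mixture_quantile <- function(p, w, sh1, rt1, sh2, rt2, iters = 80) {
  cdf <- function(x) {
    w * pgamma(x, shape = sh1, rate = rt1) +
      (1 - w) * pgamma(x, shape = sh2, rate = rt2)
  }
  lo <- 0
  hi <- max(qgamma(0.999999, sh1, rate = rt1), qgamma(0.999999, sh2, rate = rt2)) + 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random 2x2 tables in the domain the pipeline produces (target count a >= 1;
# zero-count events are never scored).
random_tables <- function(n, seed, a_min = 1L) {
  withr::with_seed(seed, tibble::tibble(
    event = sprintf("E%04d", seq_len(n)), level = "PT", target_class = "hexa",
    a = sample(a_min:50L, n, replace = TRUE),
    b = sample(0:50L, n, replace = TRUE),
    c = sample(0:50L, n, replace = TRUE),
    d = sample(0:50L, n, replace = TRUE)
  ))
}
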