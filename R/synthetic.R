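# Synthetic spontaneous-report generator: VAERS-like two-vaccine infant
# cohorts with known ground truth (planted reporting-rate ratios and a
# planted logistic death model), written in the VAERS public-extract dialect
# so the whole pipeline is testable offline.

#' Simulation configuration
#'
#' Defines the data-generating process for a synthetic two-vaccine infant
#' reporting cohort. Adverse events are drawn per PT as independent
#' Bernoulli trials with probability `min(1, baseline * rr)`, where `rr` is
#' the planted class-specific relative reporting rate; death is drawn from a
#' logistic model on age group, sex and co-administration.
#'
#' Defaults mirror the published pentavalent/hexavalent VAERS cohort: class
#' sizes 3259 and 1720, ~45% female with ~6% unknown sex, co-administration
#' in 68% of pentavalent and 88% of hexavalent reports, and a death process
#' with strongly protective older age and female effects and a harmful
#' co-administration effect.
#'
#' @param n_penta,n_hexa number of reports per vaccine class.
#' @param pt_vocab vocabulary tibble with columns `pt`, `soc`, `baseline`
#'   (per-report reporting probability in `[0, 1]`).
#' @param planted_rr `NULL` (all rates 1) or a data frame with columns `pt`,
#'   `vaccine_class` (`"penta"`/`"hexa"`) and `rr` (multiplier >= 0).
#' @param age_dist named list with elements `penta` and `hexa`, each a
#'   length-3 probability vector over age groups G1, G2, G3 (sums to 1).
#' @param p_female,p_unknown_sex sex-assignment probabilities.
#' @param p_coadmin named vector (`penta`, `hexa`): probability that a report
#'   lists at least one additional vaccine product.
#' @param death_coefs named vector of log-odds: `intercept`, `age_g2`,
#'   `age_g3`, `female`, `coadmin` (references: G1, male/unknown sex,
#'   vaccine alone).
#' @param seriousness_probs named vector of marginal probabilities for
#'   `hospitalized`, `life_threatening`, `prolonged`, `disabled` flags,
#'   drawn independently of death status.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_penta = 3259, n_hexa = 1720,
                       pt_vocab = load_pt_vocab(),
                       planted_rr = NULL,
                       age_dist = list(
                         penta = c(G1 = 0.5, G2 = 0.3, G3 = 0.2),
                         hexa = c(G1 = 0.5, G2 = 0.3, G3 = 0.2)
                       ),
                       p_female = 0.45, p_unknown_sex = 0.06,
                       p_coadmin = c(penta = 0.68, hexa = 0.88),
                       death_coefs = c(
                         intercept = -4.3, age_g2 = -1.6, age_g3 = -1.8,
                         female = -0.82, coadmin = 1.9
                       ),
                       seriousness_probs = c(
                         hospitalized = 0.10, life_threatening = 0.025,
                         prolonged = 0.005, disabled = 0.015
                       ),
                       seed = 1L) {
  cfg <- list(
    n_penta = n_penta, n_hexa = n_hexa, pt_vocab = pt_vocab,
    planted_rr = planted_rr, age_dist = age_dist, p_female = p_female,
    p_unknown_sex = p_unknown_sex, p_coadmin = p_coadmin,
    death_coefs = death_coefs, seriousness_probs = seriousness_probs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_penta) || cfg$n_penta < 0) stop_field("n_penta", "must be >= 0")
  if (!is.numeric(cfg$n_hexa) || cfg$n_hexa < 0) stop_field("n_hexa", "must be >= 0")
  v <- cfg$pt_vocab
  if (!is.data.frame(v) || !all(c("pt", "soc", "baseline") %in% names(v))) {
    stop_field("pt_vocab", "needs columns pt, soc, baseline")
  }
  if (anyDuplicated(v$pt)) stop_field("pt_vocab", "each PT must map to exactly one SOC")
  if (any(v$baseline < 0 | v$baseline > 1)) {
    stop_field("pt_vocab", "baseline probabilities must lie in [0, 1]")
  }
  for (cl in VACCINE_CLASSES) {
    p <- cfg$age_dist[[cl]]
    if (is.null(p) || length(p) != 3 || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop_field("age_dist", paste0(cl, " probabilities must be length 3 and sum to 1"))
    }
  }
  probs <- c(cfg$p_female, cfg$p_unknown_sex, cfg$p_coadmin, cfg$seriousness_probs)
  if (any(probs < 0 | probs > 1)) stop_field("probabilities", "must lie in [0, 1]")
  if (cfg$p_female + cfg$p_unknown_sex > 1) {
    stop_field("p_female", "p_female + p_unknown_sex must be <= 1")
  }
  if (!all(VACCINE_CLASSES %in% names(cfg$p_coadmin))) {
    stop_field("p_coadmin", "needs named entries penta and hexa")
  }
  needed <- c("intercept", "age_g2", "age_g3", "female", "coadmin")
  if (!all(needed %in% names(cfg$death_coefs))) {
    stop_field("death_coefs", paste("needs entries", paste(needed, collapse = ", ")))
  }
  if (!is.null(cfg$planted_rr)) {
    pr <- cfg$planted_rr
    if (!is.data.frame(pr) || !all(c("pt", "vaccine_class", "rr") %in% names(pr))) {
      stop_field("planted_rr", "needs columns pt, vaccine_class, rr")
    }
    if (!all(pr$pt %in% v$pt)) stop_field("planted_rr", "planted PTs must be in pt_vocab")
    if (!all(pr$vaccine_class %in% VACCINE_CLASSES)) {
      stop_field("planted_rr", "vaccine_class must be penta or hexa")
    }
    if (any(pr$rr < 0)) stop_field("planted_rr", "rr multipliers must be >= 0")
  }
  invisible(cfg)
}

# Per-class PT reporting probabilities: min(1, baseline * rr), warning once
# if any product exceeds 1 (clamped, not an error).
reporting_probs <- function(cfg, class) {
  rr <- rep(1, nrow(cfg$pt_vocab))
  if (!is.null(cfg$planted_rr)) {
    pr <- cfg$planted_rr[cfg$planted_rr$vaccine_class == class, , drop = FALSE]
    idx <- match(pr$pt, cfg$pt_vocab$pt)
    rr[idx] <- pr$rr
  }
  p <- cfg$pt_vocab$baseline * rr
  if (any(p > 1)) {
    warning("reporting probability exceeds 1 after rr multiplication for ",
      sum(p > 1), " PT(s) in class ", class, "; clamped to 1", call. = FALSE)
    p <- pmin(1, p)
  }
  p
}

#' Generate a synthetic reporting cohort with known truth
#'
#' Draws `n_penta + n_hexa` adverse-event reports under the configured
#' data-generating process. Each report's PT set is drawn per PT as an
#' independent Bernoulli with probability `min(1, baseline * rr)`; a report
#' drawing no PT is assigned the fallback PT `"Pyrexia"` so that no report
#' is event-free. The death indicator follows the configured logistic model;
#' other seriousness flags are independent Bernoulli draws. Output is
#' deterministic given the config (including its seed).
#'
#' @param config a [sim_config()].
#' @return a list with `reports` (the analysis-ready report tibble) and
#'   `truth` (planted relative rates, death coefficients, per-PT expected
#'   marginal counts, and per-class age-group bookkeeping).
#' @export
generate_reports <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  n <- cfg$n_penta + cfg$n_hexa
  if (n == 0) stop("invalid sim_config field 'n_penta': zero total reports")
  vocab <- cfg$pt_vocab
  class_vec <- rep(VACCINE_CLASSES, times = c(cfg$n_penta, cfg$n_hexa))

  fallback_pt <- if ("Pyrexia" %in% vocab$pt) "Pyrexia" else vocab$pt[1]

  age_group <- character(n)
  age_years <- numeric(n)
  coadmin <- logical(n)
  pts <- vector("list", n)
  bounds <- c(AGE_MIN_YEARS, AGE_G2_LO, AGE_G3_LO, AGE_MAX_YEARS)
  for (cl in VACCINE_CLASSES) {
    idx <- which(class_vec == cl)
    if (!length(idx)) next
    g <- sample.int(3, length(idx), replace = TRUE, prob = cfg$age_dist[[cl]])
    age_years[idx] <- round(stats::runif(length(idx), bounds[g], bounds[g + 1]), 2)
    coadmin[idx] <- stats::runif(length(idx)) < cfg$p_coadmin[[cl]]
    p <- reporting_probs(cfg, cl)
    # columns ordered by sorted PT name, so each report's PT set arrives
    # sorted straight out of split() with no per-report sort
    ptord <- order(vocab$pt, method = "radix")
    hits <- matrix(stats::runif(length(idx) * nrow(vocab)), nrow = length(idx)) <
      matrix(p[ptord], nrow = length(idx), ncol = nrow(vocab), byrow = TRUE)
    wh <- which(hits, arr.ind = TRUE, useNames = FALSE)
    got <- split(vocab$pt[ptord][wh[, 2]],
      factor(wh[, 1], levels = seq_along(idx)))
    # a report drawing no PT -- or only vaccination-error PTs, which describe
    # no clinical AEFI -- receives the benign fallback PT, so every synthetic
    # report survives cohort selection and report counts stay exact
    clinical <- !(vocab$pt[ptord] %in% default_error_pts())
    needs_fallback <- as.vector(hits %*% clinical) == 0
    got[needs_fallback] <- lapply(got[needs_fallback],
      function(g) sort_pts(c(g, fallback_pt)))
    pts[idx] <- unname(got)
  }
  # group recomputed from the stored (2-dp) age so bookkeeping matches readers
  age_group <- assign_age_group(age_years)

  u <- stats::runif(n)
  sex <- ifelse(u < cfg$p_female, "female",
    ifelse(u < cfg$p_female + cfg$p_unknown_sex, "unknown", "male")
  )

  b <- cfg$death_coefs
  eta <- b[["intercept"]] +
    b[["age_g2"]] * (age_group == "G2") +
    b[["age_g3"]] * (age_group == "G3") +
    b[["female"]] * (sex == "female") +
    b[["coadmin"]] * coadmin
  died <- stats::runif(n) < stats::plogis(eta)

  sp <- cfg$seriousness_probs
  hospitalized <- stats::runif(n) < sp[["hospitalized"]]
  life_threatening <- stats::runif(n) < sp[["life_threatening"]]
  prolonged_hosp <- stats::runif(n) < sp[["prolonged"]]
  disabled <- stats::runif(n) < sp[["disabled"]]

  onset <- stats::rgeom(n, 0.35)
  onset[stats::runif(n) < 0.05] <- NA_integer_
  recovered <- sample(RECOVERED_LEVELS, n, replace = TRUE,
    prob = c(0.42, 0.16, 0.32, 0.10))
  report_year <- sample(2018:2024, n, replace = TRUE)
  region <- sample(c("FR", "TX", "CA", "NY", "MI", "MA", "WA", "FL", "OH", "PA"),
    n, replace = TRUE, prob = c(0.30, 0.12, 0.10, 0.08, 0.08, 0.08, 0.07, 0.06, 0.06, 0.05))

  reports <- tibble::tibble(
    report_id = sprintf("S%06d", seq_len(n)),
    vaccine_class = factor(class_vec, levels = VACCINE_CLASSES),
    age_years = age_years,
    age_group = age_group,
    sex = factor(sex, levels = SEX_LEVELS),
    died = died,
    life_threatening = life_threatening,
    hospitalized = hospitalized,
    prolonged_hosp = prolonged_hosp,
    disabled = disabled,
    recovered = factor(recovered, levels = RECOVERED_LEVELS),
    serious = died | life_threatening | hospitalized | prolonged_hosp | disabled,
    vaccine_alone = !coadmin,
    onset_days = as.integer(onset),
    report_year = as.integer(report_year),
    region = region,
    pts = pts
  )
  # one global lookup + radix sort instead of a per-report map-and-sort
  lens <- lengths(reports$pts)
  soc_all <- suppressWarnings(map_pt_to_soc(unlist(reports$pts), vocab))
  row <- rep.int(seq_len(n), lens)
  o <- order(row, soc_all, method = "radix")
  r2 <- row[o]
  s2 <- soc_all[o]
  keep <- c(TRUE, r2[-1] != r2[-length(r2)] | s2[-1] != s2[-length(s2)])
  reports$socs <- unname(split(s2[keep], factor(r2[keep], levels = seq_len(n))))

  expected <- do.call(rbind, lapply(VACCINE_CLASSES, function(cl) {
    n_cl <- if (cl == "penta") cfg$n_penta else cfg$n_hexa
    tibble::tibble(
      pt = vocab$pt, vaccine_class = cl,
      expected_count = n_cl * suppressWarnings(reporting_probs(cfg, cl))
    )
  }))
  truth <- list(
    planted_rr = cfg$planted_rr,
    death_coefs = cfg$death_coefs,
    expected_counts = expected,
    group_sizes = as.data.frame(table(
      vaccine_class = reports$vaccine_class, age_group = reports$age_group
    ), responseName = "n")
  )
  list(reports = reports, truth = truth)
}

# ---------------------------------------------------------------------------
# VAERS-dialect writer

vax_name_for_class <- function(class) {
  c(penta = "DTAP + IPV + HIB (PENTACEL)",
    hexa = "DTAP + IPV + HEPB + HIB (VAXELIS)")[[class]]
}

vax_type_for_class <- function(class) {
  c(penta = "DTAPIPVHIB", hexa = "DTAPHEPBIP")[[class]]
}

#' Write a report collection in the VAERS public-extract dialect
#'
#' Serializes reports as the three VAERS CSV tables: `VAERSDATA.csv`
#' (report-level demographics and seriousness flags, `Y`/blank coding),
#' `VAERSVAX.csv` (one row per vaccine per report) and `VAERSSYMPTOMS.csv`
#' (five `SYMPTOM` columns per row, with overflow rows for reports carrying
#' more than five PTs). Reading the files back through
#' [read_vaers_extract()] and [select_cohort()] reproduces the records.
#'
#' @param records a report tibble as produced by [generate_reports()].
#' @param out_dir output directory (created if absent).
#' @return named character vector with the three file paths.
#' @export
write_vaers_dialect <- function(records, out_dir) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty report collection")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot write VAERS dialect: unwritable path ", out_dir)

  yn <- function(x) ifelse(x, "Y", "")
  data_tbl <- tibble::tibble(
    VAERS_ID = records$report_id,
    RECVDATE = sprintf("%d-07-01", records$report_year),
    STATE = records$region,
    AGE_YRS = sprintf("%.2f", records$age_years),
    SEX = c(male = "M", female = "F", unknown = "U")[as.character(records$sex)],
    DIED = yn(records$died),
    L_THREAT = yn(records$life_threatening),
    HOSPITAL = yn(records$hospitalized),
    X_STAY = yn(records$prolonged_hosp),
    DISABLE = yn(records$disabled),
    RECOVD = c(yes = "Y", no = "N", unknown = "U", missing = "")[
      as.character(records$recovered)],
    NUMDAYS = ifelse(is.na(records$onset_days), "", as.character(records$onset_days))
  )

  vax_rows <- lapply(seq_len(nrow(records)), function(i) {
    cl <- as.character(records$vaccine_class[i])
    rows <- data.frame(
      VAERS_ID = records$report_id[i],
      VAX_TYPE = vax_type_for_class(cl),
      VAX_NAME = vax_name_for_class(cl),
      stringsAsFactors = FALSE
    )
    if (!records$vaccine_alone[i]) {
      rows <- rbind(rows, data.frame(
        VAERS_ID = records$report_id[i],
        VAX_TYPE = "RV",
        VAX_NAME = "ROTAVIRUS (ROTATEQ)",
        stringsAsFactors = FALSE
      ))
    }
    rows
  })
  vax_tbl <- dplyr::bind_rows(vax_rows)

  sym_rows <- lapply(seq_len(nrow(records)), function(i) {
    pts <- records$pts[[i]]
    n_rows <- ceiling(length(pts) / 5)
    padded <- c(pts, rep("", n_rows * 5 - length(pts)))
    m <- matrix(padded, ncol = 5, byrow = TRUE)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- paste0("SYMPTOM", 1:5)
    cbind(VAERS_ID = records$report_id[i], out,
      SYMPTOMVERSION = "27.0", stringsAsFactors = FALSE)
  })
  sym_tbl <- dplyr::bind_rows(sym_rows)

  paths <- c(
    data = file.path(out_dir, "VAERSDATA.csv"),
    vax = file.path(out_dir, "VAERSVAX.csv"),
    symptoms = file.path(out_dir, "VAERSSYMPTOMS.csv")
  )
  readr::write_csv(data_tbl, paths[["data"]], na = "")
  readr::write_csv(vax_tbl, paths[["vax"]], na = "")
  readr::write_csv(sym_tbl, paths[["symptoms"]], na = "")
  paths
}

# ---------------------------------------------------------------------------
# Deterministic published-summary fixture

# Assign k flags per flag type over serious records 1..s, consecutively with
# wrap-around, so the union of flagged records is exactly 1..s whenever the
# flag counts sum to >= s.
flag_indices <- function(counts, s) {
  pos <- 0L
  out <- lapply(counts, function(k) {
    if (k == 0) return(integer(0))
    idx <- ((pos + seq_len(k) - 1L) %% s) + 1L
    pos <<- pos + k
    idx
  })
  names(out) <- names(counts)
  out
}

#' Deterministic cohort fixture matching the published summary table
#'
#' Builds a 4,980-report cohort (3,259 pentavalent, 1,720 hexavalent) whose
#' per-class marginal counts of sex, seriousness, each seriousness flag,
#' vaccine-alone status and recovery outcome equal the published
#' characteristics table exactly. Only the margins are constrained; the
#' joint structure (which records carry which flag combinations) is an
#' arbitrary but deterministic assignment, with seriousness flags laid out
#' consecutively over the serious block so the serious composite count is
#' exact.
#'
#' @return a report tibble in the same layout as [generate_reports()].
#' @export
table1_fixture <- function() {
  margins <- list(
    penta = list(
      n = 3259L, sex = c(male = 1588L, female = 1483L, unknown = 188L),
      serious = 440L, vaccine_alone = 1044L,
      flags = c(hospitalized = 330L, died = 70L, disabled = 61L,
        life_threatening = 48L, prolonged_hosp = 9L),
      recovered = c(yes = 1203L, no = 444L, unknown = 1328L, missing = 284L)
    ),
    hexa = list(
      n = 1720L, sex = c(male = 848L, female = 753L, unknown = 119L),
      serious = 658L, vaccine_alone = 206L,
      flags = c(hospitalized = 585L, died = 39L, disabled = 32L,
        life_threatening = 88L, prolonged_hosp = 12L),
      recovered = c(yes = 904L, no = 362L, unknown = 389L, missing = 65L)
    )
  )
  vocab <- load_pt_vocab()
  clinical_pts <- setdiff(vocab$pt, default_error_pts())
  group_ages <- c(G1 = 0.20, G2 = 0.50, G3 = 1.00)

  build_class <- function(class, s) {
    n <- s$n
    flags <- matrix(FALSE, n, 5,
      dimnames = list(NULL, names(s$flags)))
    idx <- flag_indices(s$flags, s$serious)
    for (f in names(s$flags)) flags[idx[[f]], f] <- TRUE
    sex <- rep(names(s$sex), times = s$sex)
    recovered <- rep(names(s$recovered), times = s$recovered)
    grp <- AGE_GROUPS[(seq_len(n) - 1L) %% 3L + 1L]
    tibble::tibble(
      report_id = sprintf("%s%06d", toupper(substr(class, 1, 1)), seq_len(n)),
      vaccine_class = factor(class, levels = VACCINE_CLASSES),
      age_years = unname(group_ages[grp]),
      age_group = factor(grp, levels = AGE_GROUPS),
      sex = factor(sex, levels = SEX_LEVELS),
      died = flags[, "died"],
      life_threatening = flags[, "life_threatening"],
      hospitalized = flags[, "hospitalized"],
      prolonged_hosp = flags[, "prolonged_hosp"],
      disabled = flags[, "disabled"],
      recovered = factor(recovered, levels = RECOVERED_LEVELS),
      serious = seq_len(n) <= s$serious,
      vaccine_alone = seq_len(n) <= s$vaccine_alone,
      onset_days = rep_len(c(0L, 1L, 3L, 15L, 45L, NA_integer_), n),
      report_year = rep_len(2018:2024, n),
      region = rep_len(c("FR", "TX", "MI", "CA", "NY", "MA", "WA"), n),
      pts = as.list(rep_len(clinical_pts, n))
    )
  }
  fixture <- dplyr::bind_rows(
    build_class("penta", margins$penta),
    build_class("hexa", margins$hexa)
  )
  fixture$socs <- lapply(fixture$pts, function(p) map_pt_to_soc(p, vocab))
  fixture
}
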