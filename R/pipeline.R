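# End-to-end orchestration: ingest -> cohort -> contingency tables ->
# signals -> subgroups -> death regression -> CSV/JSON outputs with a
# manifest. Every stage is a pure function of (inputs, config, seed).

#' Pipeline run configuration
#'
#' @param input input mode: `list(mode = "fixture")`,
#'   `list(mode = "synthetic", sim = sim_config(...))`, or
#'   `list(mode = "vaers_dir", dir = path)` pointing at a directory holding
#'   `VAERSDATA.csv`, `VAERSVAX.csv`, `VAERSSYMPTOMS.csv`.
#' @param cohort a [cohort_config()] (applied in `vaers_dir` mode).
#' @param target_class class whose events are scored against the other.
#' @param levels event levels to score, subset of `c("PT", "SOC")`.
#' @param strata stratification factors for subgroup analyses.
#' @param top_k K for the most-frequent-PT tables.
#' @param out_dir output directory.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(input = list(mode = "fixture"),
                       cohort = cohort_config(),
                       target_class = c("hexa", "penta"),
                       levels = c("PT", "SOC"),
                       strata = c("age_group", "sex"),
                       top_k = 20,
                       out_dir = tempfile("aefisignal_run_"),
                       seed = 1L) {
  stopifnot(is.list(input), !is.null(input$mode))
  if (!input$mode %in% c("fixture", "synthetic", "vaers_dir")) {
    stop("run_config: input$mode must be fixture, synthetic or vaers_dir")
  }
  levels <- match.arg(levels, several.ok = TRUE)
  strata <- match.arg(strata, c("age_group", "sex", "serious"), several.ok = TRUE)
  structure(list(
    input = input, cohort = cohort,
    target_class = match.arg(target_class),
    levels = levels, strata = strata, top_k = top_k,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror [run_config()]; `input.sim` entries, when present, are
#' passed to [sim_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  input <- raw$input %||% list(mode = "fixture")
  if (identical(input$mode, "synthetic")) {
    sim_args <- input$sim %||% list()
    input$sim <- do.call(sim_config, sim_args)
  }
  run_config(
    input = input,
    cohort = do.call(cohort_config, raw$cohort %||% list()),
    target_class = raw$target_class %||% "hexa",
    levels = raw$levels %||% c("PT", "SOC"),
    strata = raw$strata %||% c("age_group", "sex"),
    top_k = raw$top_k %||% 20,
    out_dir = raw$out_dir %||% tempfile("aefisignal_run_"),
    seed = raw$seed %||% 1L
  )
}

write_stage_csv <- function(tbl, out_dir, name, manifest) {
  path <- file.path(out_dir, name)
  flat <- tbl
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = "; ")
    }
  }
  readr::write_csv(flat, path, na = "")
  manifest$files[[name]] <- list(path = name, rows = nrow(tbl))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes ingest, cohort summary, contingency-table construction, signal
#' scoring at each configured level, subgroup analyses, top-K PT ranking
#' and the per-class death regression, writing each product as CSV under
#' `out_dir` plus a JSON `manifest.json` recording row counts, the seed,
#' a configuration hash and the package version. Identical configuration
#' and seed give byte-identical tracked outputs. A failing stage aborts
#' with the stage name after writing the partial manifest.
#'
#' @param config a [run_config()].
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("aefisignal")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    stages = list(), files = list()
  )
  stage <- "ingest"
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run <- function() {
    reports <- switch(config$input$mode,
      fixture = table1_fixture(),
      synthetic = {
        sim <- config$input$sim %||% sim_config(seed = derive_seed(config$seed, 1L))
        generate_reports(sim)$reports
      },
      vaers_dir = {
        d <- config$input$dir
        raw <- read_vaers_extract(
          file.path(d, "VAERSDATA.csv"),
          file.path(d, "VAERSVAX.csv"),
          file.path(d, "VAERSSYMPTOMS.csv")
        )
        select_cohort(raw, config$cohort)
      }
    )
    manifest$stages$ingest <<- list(mode = config$input$mode, n_reports = nrow(reports))

    stage <<- "cohort_summary"
    summ <- summarize_cohort(reports)
    manifest <<- write_stage_csv(summ$characteristics, config$out_dir,
      "cohort_characteristics.csv", manifest)
    manifest <<- write_stage_csv(summ$by_year, config$out_dir, "cohort_by_year.csv", manifest)
    manifest <<- write_stage_csv(summ$onset_bins, config$out_dir, "cohort_onset_bins.csv", manifest)
    manifest <<- write_stage_csv(summ$by_region, config$out_dir, "cohort_by_region.csv", manifest)
    manifest$stages$cohort_summary <<- list(
      n = nrow(reports),
      n_by_class = as.list(table(reports$vaccine_class))
    )

    stage <<- "signals"
    for (level in config$levels) {
      tables <- build_all_tables(reports, level = level,
        target_class = config$target_class)
      manifest <<- write_stage_csv(tables, config$out_dir,
        sprintf("contingency_%s.csv", tolower(level)), manifest)
      signals <- compute_signals(tables)
      manifest <<- write_stage_csv(signals, config$out_dir,
        sprintf("signals_%s.csv", tolower(level)), manifest)
      manifest$stages[[paste0("signals_", tolower(level))]] <<- list(
        n_events = nrow(signals), n_consensus = sum(signals$consensus))
    }

    stage <<- "subgroups"
    for (f in config$strata) {
      sub <- subgroup_signals(reports, factor = f, level = "PT",
        target_class = config$target_class)
      manifest <<- write_stage_csv(sub, config$out_dir,
        sprintf("subgroup_signals_%s.csv", f), manifest)
      strata <- stratify(reports, f)
      topk <- dplyr::bind_rows(lapply(names(strata), function(lv) {
        tk <- suppressWarnings(top_k_pts(reports, k = config$top_k,
          target_class = config$target_class,
          stratum = list(factor = f, level = lv)))
        if (nrow(tk)) dplyr::bind_cols(tibble::tibble(stratum = lv), tk) else NULL
      }))
      manifest <<- write_stage_csv(topk, config$out_dir,
        sprintf("top%d_pt_%s.csv", config$top_k, f), manifest)
      manifest$stages[[paste0("subgroup_", f)]] <<- list(
        n_strata = length(strata),
        stratum_n = lapply(strata, nrow)
      )
    }

    stage <<- "death_model"
    for (cl in VACCINE_CLASSES) {
      fit <- tryCatch(fit_death_model(reports, cl), error = function(err) err)
      if (inherits(fit, "error")) {
        manifest$stages[[paste0("death_model_", cl)]] <<- list(
          fitted = FALSE, reason = conditionMessage(fit))
        next
      }
      manifest <<- write_stage_csv(fit$terms, config$out_dir,
        sprintf("death_model_%s.csv", cl), manifest)
      manifest$stages[[paste0("death_model_", cl)]] <<- list(
        fitted = TRUE, n_used = fit$n_used,
        n_excluded_unknown_sex = fit$n_excluded_unknown_sex,
        iterations = fit$iterations)
    }
    stage <<- "manifest"
  }
  result <- tryCatch({ run(); TRUE }, error = function(err) err)
  finish()
  if (inherits(result, "error")) {
    stop("run_pipeline: stage '", stage, "' failed: ",
      conditionMessage(result), call. = FALSE)
  }
  message("run_pipeline: completed; outputs in ", config$out_dir)
  invisible(manifest)
}
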