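# NONMEM-style dataset IO, run configuration, and pipeline orchestration.

DATASET_COLUMNS <- c("ID", "OCC", "TIME", "DV", "AMT", "RATE", "EVID", "MDV",
                     "CENS", "LLOQ", "BW", "DOSEGRP")

# Schema validation shared by the readers and the analysis entry points.
.validate_dataset <- function(data, context = "dataset") {
  if (!is.data.frame(data)) abort(sprintf("%s must be a data frame.", context))
  if (nrow(data) == 0L) abort(sprintf("%s is empty (no rows).", context))
  missing_cols <- setdiff(DATASET_COLUMNS, names(data))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  context, paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  row_err <- function(bad, what) {
    if (any(bad)) {
      abort(sprintf("%s: %s in row(s) %s.", context, what,
                    paste(utils::head(which(bad), 5), collapse = ", ")))
    }
  }
  row_err(!is.finite(data$TIME) | data$TIME < 0, "negative or missing TIME")
  dose <- data$EVID == 1L
  row_err(dose & (!is.finite(data$AMT) | data$AMT <= 0),
          "dose event with non-positive AMT")
  row_err(dose & (!is.finite(data$RATE) | data$RATE <= 0),
          "dose event with non-positive RATE")
  row_err(dose & data$MDV != 1L, "dose event with MDV != 1")
  obs <- data$EVID == 0L
  row_err(obs & data$CENS == 0L & !is.finite(data$DV),
          "observation with missing DV and CENS = 0")
  row_err(obs & is.finite(data$DV) & data$DV < 0, "negative DV")
  no_dose <- setdiff(unique(data$ID), unique(data$ID[dose]))
  if (length(no_dose)) {
    abort(sprintf("%s: subject(s) without any dose event: %s.",
                  context, paste(no_dose, collapse = ", ")))
  }
  data
}

#' Read / write the NONMEM-style dataset CSV
#'
#' The dataset dialect has one row per event, with columns `ID`, `OCC`
#' (occasion), `TIME` (h), `DV` (concentration, mM), `AMT` (dose, mg),
#' `RATE` (mg/h), `EVID` (1 = dose, 0 = observation), `MDV`, `CENS`
#' (1 = below the quantification limit), `LLOQ` (mM), `BW` (kg), `DOSEGRP`
#' (mg/kg). Reading validates the schema and reports offending rows;
#' writing then reading a dataset is lossless.
#'
#' @param path CSV file path.
#' @return `read_pkdataset()`: a validated tibble. `write_pkdataset()`: the
#'   input, invisibly.
#' @export
read_pkdataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Could not parse %s as CSV: %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(data) == 0L) {
    abort(sprintf("%s contains no data rows (empty dataset).", path))
  }
  data <- .validate_dataset(data, context = path)
  for (col in c("ID", "OCC", "EVID", "MDV", "CENS")) {
    data[[col]] <- as.integer(data[[col]])
  }
  data
}

#' @param data Dataset tibble conforming to the schema.
#' @rdname read_pkdataset
#' @export
write_pkdataset <- function(data, path) {
  data <- .validate_dataset(data)
  out <- data[DATASET_COLUMNS]
  # serialise doubles at full precision so write -> read is bit-lossless
  for (col in c("TIME", "DV", "AMT", "RATE", "LLOQ", "BW", "DOSEGRP")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.17g", out[[col]]))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(data)
}

#' Pipeline run configuration
#'
#' A nested list controlling the end-to-end pipeline: `design` (arguments of
#' [study_design()]), `params` (arguments of [pop_params()]; simulation truth
#' and SAEM initials), `saem` (arguments of [saem_settings()]), `nca`
#' (`css_window`, `baseline_subtract`), `vpc` (`n_individuals`, `time_step`),
#' `seed`, and `output_dir`. `run_config()` builds one from defaults;
#' `read_run_config()` loads YAML or JSON (by extension) and merges it over
#' the defaults, rejecting unknown keys by name. A configuration
#' round-trips unchanged through YAML.
#'
#' @param ... Overrides for the top-level blocks.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    design = list(), params = list(), saem = list(),
    nca = list(css_window = NULL, baseline_subtract = FALSE),
    vpc = list(n_individuals = 2000, time_step = 0.05),
    seed = 1L, output_dir = "ascorbpk-run"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      .merge_block(base[[nm]], over[[nm]], nm)
    } else {
      over[[nm]]
    }
  }
  structure(base, class = "run_config")
}

.merge_block <- function(base, over, block) {
  known <- switch(block,
    design = names(formals(study_design)),
    params = names(formals(pop_params)),
    saem = names(formals(saem_settings)),
    nca = c("css_window", "baseline_subtract"),
    vpc = c("n_individuals", "time_step"),
    names(base)
  )
  unknown <- setdiff(names(over), known)
  if (length(unknown)) {
    abort(sprintf("Unknown key(s) in `%s` block: %s.",
                  block, paste(unknown, collapse = ", ")))
  }
  utils::modifyList(base, over)
}

#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("Unsupported config format `.%s` (use YAML or JSON).", ext))
  )
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> fit -> NCA -> VPC on a synthetic study and
#' writes all artifacts to the output directory: `dataset.csv`,
#' `fit.json` (estimates, likelihood, BIC, convergence), `nca_individual.csv`,
#' `nca_summary.csv`, `vpc_bands.csv`, and `manifest.json` (seed, settings,
#' package version, wall time). All randomness flows from the single
#' configuration seed, so two runs with the same configuration produce
#' identical numeric artifacts. A failing stage aborts with the stage name
#' and a reproduction hint.
#'
#' @param config A [run_config()].
#' @param output_dir Override of `config$output_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`data`, `fit`,
#'   `nca`, `nca_summary`, `vpc`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    abort("`config` must come from `run_config()` or `read_run_config()`.")
  }
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf(
        "Pipeline stage `%s` failed: %s\nReproduce with run_pipeline(<same config>) after fixing the input.",
        name, conditionMessage(e)))
    })
  }
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed
  design <- do.call(study_design, config$design)
  truth <- do.call(pop_params, utils::modifyList(
    as.list(unclass(ascorbate_pop_params())), config$params))
  settings <- do.call(saem_settings,
                      utils::modifyList(config$saem, list(seed = seed + 1L)))

  say("Stage generate: %d subjects, %d dose level(s), seed %d",
      design$n_subjects, length(design$dose_levels), seed)
  data <- stage("generate", generate_study(design, truth, seed = seed))
  path_data <- file.path(out_dir, "dataset.csv")
  stage("generate", write_pkdataset(data, path_data))

  say("Stage fit: SAEM %d + %d iterations, seed %d",
      settings$n_exploratory, settings$n_smoothing, seed + 1L)
  fit <- stage("fit", saem(data, init = truth, settings = settings))
  path_fit <- file.path(out_dir, "fit.json")
  stage("fit", jsonlite::write_json(list(
    estimates = tidy(fit), glance = glance(fit),
    individual = fit$individual,
    convergence = fit$convergence
  ), path_fit, dataframe = "columns", auto_unbox = TRUE, digits = NA))

  say("Stage nca")
  nca_res <- stage("nca", nca(data,
                              css_window = config$nca$css_window,
                              baseline_subtract = isTRUE(config$nca$baseline_subtract)))
  nca_sum <- stage("nca", nca_summary(nca_res))
  path_nca <- file.path(out_dir, "nca_individual.csv")
  path_nca_sum <- file.path(out_dir, "nca_summary.csv")
  readr::write_csv(nca_res, path_nca, progress = FALSE)
  readr::write_csv(nca_sum, path_nca_sum, progress = FALSE)

  say("Stage vpc: %d individuals", config$vpc$n_individuals)
  vpc <- stage("vpc", simulate_prediction_bands(
    fit$estimates, design,
    n_individuals = config$vpc$n_individuals,
    time_step = config$vpc$time_step, seed = seed + 2L))
  path_vpc <- file.path(out_dir, "vpc_bands.csv")
  readr::write_csv(as_tibble(vpc), path_vpc, progress = FALSE)

  manifest <- list(
    package = "ascorbpk",
    version = as.character(packageVersion("ascorbpk")),
    seed = seed,
    design = config$design, params = config$params,
    saem = config$saem[setdiff(names(config$saem), "seed")],
    converged = fit$converged,
    wall_time_s = proc.time()[["elapsed"]] - t0
  )
  path_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path_manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(
    data = data, fit = fit, nca = nca_res, nca_summary = nca_sum, vpc = vpc,
    paths = list(dataset = path_data, fit = path_fit, nca = path_nca,
                 nca_summary = path_nca_sum, vpc = path_vpc,
                 manifest = path_manifest)
  ))
}
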