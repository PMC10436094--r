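check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0(what, " is missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tillerscope_schema_error")
  }
  invisible(df)
}

#' Read the pipeline's input CSVs
#'
#' Readers for the three input schemas: daily weather (one row per
#' site-year and date), soil characterisation (one row per site-year) and
#' plot observations (one row per measurement). Dates are ISO-8601. Missing
#' required columns are an error naming the column.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_weather_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("site_year", "date", "t_min", "t_max", "radiation",
                      "vpd", "precip"), "Weather table")
  df$date <- as.Date(df$date)
  if (!"irrigation" %in% names(df)) df$irrigation <- 0
  if (any(df$vpd < 0) || any(df$precip < 0) || any(df$radiation < 0) ||
      any(df$irrigation < 0)) {
    rlang::abort("Weather table contains negative radiation/vpd/precip/irrigation",
                 class = "tillerscope_weather_error")
  }
  df
}

#' @rdname read_weather_csv
#' @export
read_soil_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, soil_required_cols, "Soil table")
  df
}

#' @rdname read_weather_csv
#' @export
read_observations_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("site_year", "season", "genotype", "stage", "sow_date",
                      "obs_date", "observed_pd", "tiller_density"),
                "Observations table")
  df$sow_date <- as.Date(df$sow_date)
  df$obs_date <- as.Date(df$obs_date)
  df
}

#' Write a synthetic dataset to disk
#'
#' Emits the three input CSVs ([read_weather_csv()] schemas) plus a
#' `truth.json` recording the seed, noise model, intercept and effect
#' parameters of the generating truth.
#'
#' @param sim Result of [generate_tiller_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    weather = file.path(dir, "weather.csv"),
    soil = file.path(dir, "soil.csv"),
    observations = file.path(dir, "observations.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(sim$weather, paths["weather"])
  readr::write_csv(sim$soil, paths["soil"])
  readr::write_csv(sim$observations, paths["observations"])
  tm <- sim$truth_manifest
  truth_json <- list(
    seed = tm$seed,
    intercept = tm$truth$intercept,
    noise = tm$truth$noise, rho = tm$truth$rho, sd = tm$truth$sd,
    effects = lapply(tm$truth$effects, function(ef) {
      list(covariate = ef$covariate, type = ef$type,
           seasons = ef$seasons, params = ef$params)
    })
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Run manifest for reproducible pipeline runs
#'
#' Records what a run saw: the seed(s), a hash of the constants
#' configuration, checksums of any input files, the package version and a
#' timestamp. Two runs with identical manifests (ignoring the timestamp)
#' reproduce identical outputs.
#'
#' @param seed Integer seed(s) used.
#' @param consts A [tiller_constants()].
#' @param inputs Character vector of input file paths to checksum.
#' @param extra Named list of additional fields to record.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seed, consts = tiller_constants(),
                         inputs = character(), extra = list()) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else list()
  structure(
    c(list(
      seed = seed,
      constants = unclass(consts),
      input_checksums = checksums,
      package_version = as.character(utils::packageVersion("tillerscope")),
      timestamp = format(Sys.time(), tz = "UTC")
    ), extra),
    class = "run_manifest"
  )
}

#' Write a run manifest, evaluation report or attribution table
#'
#' Reports go to CSV (one row per candidate or attribution entry);
#' manifests go to JSON.
#'
#' @param x A `tiller_evaluation`, `tiller_attribution` or `run_manifest`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "run_manifest")) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::as_tibble(x), path)
  }
  invisible(path)
}

#' Run the full tiller-density pipeline on input tables
#'
#' Convenience orchestration: derives covariates, ranks the candidate
#' registry on a cross-season split, refits the selected candidate on the
#' full training set, runs out-of-season attribution, and extracts
#' 0.50-probability thresholds for every smooth term of the selected
#' candidate by density class.
#'
#' @param observations,weather,soil Input tibbles (see
#'   [derive_covariates()]).
#' @param registry Candidate registry (default [candidate_registry()]).
#' @param seed Integer seed for the cross-season split.
#' @param consts A [tiller_constants()].
#' @return List with `covariates`, `evaluation`, `selected_fit`,
#'   `attribution`, `thresholds`, `manifest`.
#' @export
run_pipeline <- function(observations, weather, soil,
                         registry = candidate_registry(), seed = 1,
                         consts = tiller_constants()) {
  covariates <- derive_covariates(observations, weather, soil, consts)
  split <- cross_season_split(covariates, seed = seed)
  evaluation <- rank_candidates(covariates, split, registry, consts)
  best_name <- evaluation$candidate[evaluation$selected]
  best_spec <- registry[[best_name]]
  fit <- fit_tiller_model(covariates[split$train, , drop = FALSE], best_spec,
                          consts)
  attribution <- attribute_errors(covariates, best_spec, consts = consts)
  classes <- if ("pd_class" %in% spec_covariates(best_spec))
    names(PD_TARGETS) else list(NULL)
  thresholds <- purrr::map_dfr(best_spec$smooths, function(v) {
    purrr::map_dfr(classes, function(cl) {
      extract_thresholds(response_curve(fit, v, pd_class = cl),
                         prob = consts$prob_threshold)
    })
  })
  list(
    covariates = covariates, evaluation = evaluation, selected_fit = fit,
    attribution = attribution, thresholds = thresholds,
    manifest = run_manifest(seed, consts,
                            extra = list(selected_candidate = best_name))
  )
}
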