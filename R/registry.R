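# Covariates a candidate may smooth over, and the factors it may include.
SMOOTH_COVARIATES <- c("gdd", "ptq", "t_min_mean", "t_max_mean", "t_amp_mean",
                       "cm", "vpd_cum", "observed_pd", "ph", "om", "no3_kg",
                       "nh4_kg", "p_kg", "cec", "sand", "silt", "clay")
FACTOR_COVARIATES <- c("genotype", "pd_class")

#' Define a candidate model structure
#'
#' A candidate is a set of thin-plate smooth terms over continuous
#' covariates, an optional factor-by structure (a separate smooth per level
#' of plant-density class, genotype, or their crossing), and categorical main
#' effects. Interaction ("x") candidates use factor-by smooths; additive
#' ("+") candidates share one smooth per covariate.
#'
#' @param name Candidate label.
#' @param smooths Character vector of continuous covariates to smooth
#'   (columns of the covariate table, e.g. `"gdd"`, `"vpd_cum"`, `"p_kg"`).
#' @param by Factor-by structure: `"none"`, `"pd_class"`, `"genotype"`, or
#'   `"genotype_pd_class"` (one smooth per genotype-by-density-class cell).
#' @param factors Categorical main effects (`"genotype"`, `"pd_class"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, smooths, by = "none", factors = character()) {
  by <- match.arg(by, c("none", "pd_class", "genotype", "genotype_pd_class"))
  bad <- setdiff(smooths, SMOOTH_COVARIATES)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown smooth covariate(s): ",
                        paste(bad, collapse = ", ")),
                 class = "tillerscope_spec_error")
  }
  bad <- setdiff(factors, FACTOR_COVARIATES)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown factor covariate(s): ",
                        paste(bad, collapse = ", ")),
                 class = "tillerscope_spec_error")
  }
  structure(list(name = name, smooths = smooths, by = by,
                 factors = factors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s\n  smooths: %s\n  by: %s\n  factors: %s\n",
              x$name, paste(x$smooths, collapse = ", "), x$by,
              if (length(x$factors)) paste(x$factors, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' The registry of tiller-density model candidates
#'
#' Returns the fifteen candidate structures evaluated against each other:
#' combinations of temporal, weather, soil, environment (E), management (M)
#' and genotype (G) predictor groups, in additive ("+") and interaction
#' ("x") forms. Simplified interaction candidates involving management
#' encode the plant-density interaction as factor-by smooths over the three
#' density classes; interaction candidates involving genotype extend the
#' same device to genotype levels.
#'
#' @return Named list of [model_spec()] objects.
#' @export
#' @examples
#' names(candidate_registry())
#' candidate_registry()[["E x M"]]
candidate_registry <- function() {
  key_env <- c("gdd", "ptq", "t_min_mean", "t_max_mean", "vpd_cum",
               "no3_kg", "p_kg")
  specs <- list(
    model_spec("Full",
               smooths = c("gdd", "ptq", "t_min_mean", "t_max_mean",
                           "t_amp_mean", "cm", "vpd_cum", "observed_pd",
                           "ph", "om", "no3_kg", "nh4_kg", "p_kg", "cec",
                           "sand", "silt", "clay"),
               factors = "genotype"),
    model_spec("Temporal", smooths = c("gdd", "ptq")),
    model_spec("Weather",
               smooths = c("gdd", "ptq", "t_min_mean", "t_max_mean",
                           "t_amp_mean", "cm", "vpd_cum")),
    model_spec("Soil",
               smooths = c("ph", "om", "no3_kg", "nh4_kg", "p_kg", "cec",
                           "sand", "silt", "clay")),
    model_spec("E",
               smooths = c("gdd", "t_min_mean", "t_max_mean", "t_amp_mean",
                           "cm", "vpd_cum", "ph", "om", "no3_kg", "nh4_kg",
                           "p_kg", "cec", "sand", "silt", "clay")),
    model_spec("M",
               smooths = c("gdd", "cm", "observed_pd", "ph", "no3_kg",
                           "nh4_kg", "p_kg"),
               factors = "genotype"),
    model_spec("Stress",
               smooths = c("t_min_mean", "t_max_mean", "cm", "vpd_cum")),
    model_spec("G + E", smooths = key_env, factors = "genotype"),
    model_spec("G x E", smooths = key_env, by = "genotype",
               factors = "genotype"),
    model_spec("E + M", smooths = c(key_env, "observed_pd")),
    model_spec("E x M", smooths = key_env, by = "pd_class",
               factors = "pd_class"),
    model_spec("G + M", smooths = "observed_pd", factors = "genotype"),
    model_spec("G x M", smooths = "observed_pd", by = "genotype",
               factors = "genotype"),
    model_spec("G + E + M", smooths = c(key_env, "observed_pd"),
               factors = "genotype"),
    model_spec("G x E x M", smooths = key_env, by = "genotype_pd_class",
               factors = c("genotype", "pd_class"))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
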