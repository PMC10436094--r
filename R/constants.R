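#' Pipeline constants
#'
#' Fixed configuration used throughout the pipeline: the thermal-time base and
#' cap, the assumed maximum attainable tiller density, the pre-sowing window
#' for cumulative moisture, the probability defining a limiting threshold, and
#' soil sampling depths for the nutrient mass conversion.
#'
#' Defaults follow standard practice for maize in the U.S. Central High
#' Plains: a 10 degC crop base temperature with daily mean temperature capped
#' at 30 degC, a ceiling of 300000 tillers per hectare (3 tillers per plant at
#' a maximised stand of 100000 plants per hectare), nitrate and ammonium
#' sampled to 60 cm and Mehlich phosphorus to 15 cm.
#'
#' @param t_base Crop base temperature (degC) for growing degree days.
#' @param t_cap Cap (degC) applied to daily temperature before subtracting
#'   the base.
#' @param y_max Maximum attainable tiller density (tillers per hectare); the
#'   binomial trial count.
#' @param pre_sow_window Days before sowing included in cumulative moisture.
#' @param prob_threshold Probability level defining a limiting threshold on a
#'   response curve.
#' @param no3_depth,nh4_depth,p_depth Soil sampling depths (cm) used when
#'   converting nutrient concentrations to areal masses.
#' @param gdd_cap Where the 30 degC cap is applied: `"mean"` caps the daily
#'   mean temperature (default), `"tmax"` caps the daily maximum before
#'   averaging (a common agronomic variant).
#' @param family Binomial family used for model fitting: `"quasibinomial"`
#'   (default; the large trial count makes nominal binomial variance
#'   unrealistically small) or `"binomial"`.
#' @param method Smoothing-parameter selection method passed to the fitter
#'   (`"REML"` default, or `"GCV.Cp"`).
#' @param basis_dim Basis dimension `k` per thin-plate smooth.
#'
#' @return A list of class `tiller_constants`.
#' @export
#' @examples
#' consts <- tiller_constants()
#' consts$y_max
tiller_constants <- function(t_base = 10,
                             t_cap = 30,
                             y_max = 300000,
                             pre_sow_window = 30,
                             prob_threshold = 0.5,
                             no3_depth = 60,
                             nh4_depth = 60,
                             p_depth = 15,
                             gdd_cap = c("mean", "tmax"),
                             family = c("quasibinomial", "binomial"),
                             method = c("REML", "GCV.Cp"),
                             basis_dim = 10) {
  gdd_cap <- match.arg(gdd_cap)
  family <- match.arg(family)
  method <- match.arg(method)
  stopifnot(t_base < t_cap, y_max > 0, pre_sow_window >= 0,
            prob_threshold > 0, prob_threshold < 1,
            no3_depth > 0, nh4_depth > 0, p_depth > 0, basis_dim >= 3)
  structure(
    list(t_base = t_base, t_cap = t_cap, y_max = y_max,
         pre_sow_window = pre_sow_window, prob_threshold = prob_threshold,
         no3_depth = no3_depth, nh4_depth = nh4_depth, p_depth = p_depth,
         gdd_cap = gdd_cap, family = family, method = method,
         basis_dim = basis_dim),
    class = "tiller_constants"
  )
}

#' Load constants overrides from a YAML config file
#'
#' Reads a YAML file whose top-level keys are arguments of
#' [tiller_constants()] and returns the merged constants object. Unknown keys
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tiller_constants` list.
#' @export
load_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(tiller_constants))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown constants key(s) in config: ",
                        paste(bad, collapse = ", ")),
                 class = "tillerscope_config_error")
  }
  do.call(tiller_constants, cfg)
}

#' @export
print.tiller_constants <- function(x, ...) {
  cat("<tiller_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
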