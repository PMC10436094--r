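#' Daily growing degree days
#'
#' Thermal time accrued in one day: the difference between mean daily
#' temperature and the crop base temperature, with the daily value capped at
#' the forced maximum before subtraction and floored at zero. Mean daily
#' temperature is `(t_min + t_max) / 2`. With `gdd_cap = "tmax"` in the
#' constants the cap is instead applied to `t_max` before averaging.
#'
#' @param t_min,t_max Daily minimum and maximum air temperature (degC);
#'   vectorised.
#' @param consts A [tiller_constants()] object.
#' @return Numeric vector of daily degree days (degC day). With the default
#'   10/30 degC base and cap the value always lies in \[0, 20\].
#' @export
#' @examples
#' daily_gdd(20, 30)  # mean 25 -> 15
#' daily_gdd(32, 38)  # mean 35, capped at 30 -> 20
#' daily_gdd(4, 12)   # mean 8, below base -> 0
daily_gdd <- function(t_min, t_max, consts = tiller_constants()) {
  stopifnot(length(t_min) == length(t_max))
  if (any(t_min > t_max, na.rm = TRUE)) {
    rlang::abort("t_min exceeds t_max in weather input",
                 class = "tillerscope_weather_error")
  }
  if (consts$gdd_cap == "tmax") {
    t_mean <- (t_min + pmin(t_max, consts$t_cap)) / 2
  } else {
    t_mean <- pmin((t_min + t_max) / 2, consts$t_cap)
  }
  pmax(0, t_mean - consts$t_base)
}

# Extract the rows of a single-site daily weather table covering [from, to],
# erroring on the first missing calendar day. Dates must be Date.
slice_window <- function(weather, from, to, what = "weather") {
  if (to < from) {
    rlang::abort("Observation window ends before it starts",
                 class = "tillerscope_window_error")
  }
  days <- seq(from, to, by = "day")
  idx <- match(days, weather$date)
  if (anyNA(idx)) {
    missing_day <- days[which(is.na(idx))[1]]
    rlang::abort(
      sprintf("Missing %s for %s (first missing day in window %s to %s)",
              what, format(missing_day), format(from), format(to)),
      class = "tillerscope_missing_day_error"
    )
  }
  weather[idx, , drop = FALSE]
}

#' Cumulative growing degree days over a window
#'
#' Sums [daily_gdd()] over the closed window from sowing to observation date.
#'
#' @param weather Daily weather tibble for one site-year with columns `date`,
#'   `t_min`, `t_max`.
#' @param sow_date,obs_date Window endpoints (both included). A window
#'   ending on its start date has accrued nothing and returns 0.
#' @inheritParams daily_gdd
#' @return Cumulative degree days (degC day), non-decreasing in `obs_date`.
#' @export
cumulative_gdd <- function(weather, sow_date, obs_date,
                           consts = tiller_constants()) {
  if (obs_date == sow_date) return(0)
  w <- slice_window(weather, sow_date, obs_date)
  sum(daily_gdd(w$t_min, w$t_max, consts))
}

#' Photothermal quotient over a window
#'
#' Mean daily solar radiation for the window divided by the difference
#' between the window's mean temperature and the crop base temperature.
#' Units MJ m^-2 degC^-1 day^-1.
#'
#' @inheritParams cumulative_gdd
#' @return Scalar photothermal quotient.
#' @export
photothermal_quotient <- function(weather, sow_date, obs_date,
                                  consts = tiller_constants()) {
  w <- slice_window(weather, sow_date, obs_date)
  denom <- mean((w$t_min + w$t_max) / 2) - consts$t_base
  if (denom <= 0) {
    rlang::abort(
      sprintf(paste0("Degenerate photothermal quotient: window mean ",
                     "temperature (%.2f degC) does not exceed the base ",
                     "temperature (%g degC)"),
              mean((w$t_min + w$t_max) / 2), consts$t_base),
      class = "tillerscope_degenerate_period_error"
    )
  }
  mean(w$radiation) / denom
}

#' Cumulative vapour pressure deficit over a window
#'
#' @inheritParams cumulative_gdd
#' @return Sum of daily VPD (kPa) over the closed window.
#' @export
cumulative_vpd <- function(weather, sow_date, obs_date) {
  if (obs_date == sow_date) return(0)
  w <- slice_window(weather, sow_date, obs_date)
  sum(w$vpd)
}

#' Cumulative moisture supply
#'
#' Precipitation plus irrigation summed from `pre_sow_window` days before
#' sowing through the observation date, approximating soil moisture at
#' planting plus in-season supply.
#'
#' @inheritParams cumulative_gdd
#' @return Cumulative moisture (mm).
#' @export
cumulative_moisture <- function(weather, sow_date, obs_date,
                                consts = tiller_constants()) {
  from <- sow_date - consts$pre_sow_window
  w <- slice_window(weather, from, obs_date)
  irr <- if ("irrigation" %in% names(w)) w$irrigation else 0
  sum(w$precip + irr)
}

#' Window temperature means
#'
#' Mean daily minimum and maximum temperature and mean daily thermal
#' amplitude (`t_max - t_min`) over the closed window.
#'
#' @inheritParams cumulative_gdd
#' @return Named list with `t_min_mean`, `t_max_mean`, `t_amp_mean` (degC).
#' @export
temp_means <- function(weather, sow_date, obs_date) {
  w <- slice_window(weather, sow_date, obs_date)
  list(t_min_mean = mean(w$t_min),
       t_max_mean = mean(w$t_max),
       t_amp_mean = mean(w$t_max - w$t_min))
}

#' Convert a soil nutrient concentration to an areal mass
#'
#' Converts a gravimetric concentration (mg per kg soil) to a mass per unit
#' area (kg per hectare) over the sampled depth:
#' `conc * bulk_density * depth_m * 10`. The factor 10 carries the units:
#' one hectare to `depth_m` at `bulk_density` Mg m^-3 holds
#' `1e7 * depth_m * bulk_density` kg of soil, and mg kg^-1 is 1e-6 kg kg^-1.
#'
#' @param conc Concentration (mg kg^-1); vectorised.
#' @param bulk_density Soil bulk density (Mg m^-3).
#' @param depth Sampling depth (cm).
#' @return Areal nutrient mass (kg ha^-1).
#' @export
#' @examples
#' nutrient_mass(26.8, 1.3, 60)  # 209.04 kg/ha
nutrient_mass <- function(conc, bulk_density, depth) {
  if (any(conc < 0)) {
    rlang::abort("Negative nutrient concentration",
                 class = "tillerscope_soil_error")
  }
  if (any(bulk_density <= 0) || any(depth <= 0)) {
    rlang::abort("Bulk density and sampling depth must be positive",
                 class = "tillerscope_soil_error")
  }
  conc * bulk_density * (depth / 100) * 10
}

# Target plant densities (plants/ha) anchoring the three density classes.
PD_TARGETS <- c(A = 25000, B = 42000, C = 60000)

#' Classify observed plant density into target clusters
#'
#' Assigns each realised plant density to the nearest of the three target
#' densities (25000, 42000, 60000 plants ha^-1), labelled `A`, `B`, `C`.
#' Exact ties go to the lower target (conservative toward more tillering).
#'
#' @param observed_pd Observed plant density (plants ha^-1, > 0); vectorised.
#' @return Factor with levels `A`, `B`, `C`.
#' @export
#' @examples
#' classify_plant_density(c(30000, 41295, 33500))
classify_plant_density <- function(observed_pd) {
  if (any(observed_pd <= 0)) {
    rlang::abort("Observed plant density must be positive",
                 class = "tillerscope_observation_error")
  }
  cls <- vapply(observed_pd, function(pd) {
    d <- abs(PD_TARGETS - pd)
    names(PD_TARGETS)[which.min(d)]  # which.min takes the first (lower) tie
  }, character(1))
  factor(cls, levels = names(PD_TARGETS))
}

soil_required_cols <- c("site_year", "ph", "om", "no3_conc", "nh4_conc",
                        "p_conc", "cec", "sand", "silt", "clay",
                        "bulk_density")

# Validate a soil table and append areal nutrient masses.
prepare_soil <- function(soil, consts = tiller_constants()) {
  missing <- setdiff(soil_required_cols, names(soil))
  if (length(missing) > 0) {
    rlang::abort(paste0("Soil table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tillerscope_schema_error")
  }
  tex <- soil$sand + soil$silt + soil$clay
  if (any(abs(tex - 100) > 0.5)) {
    rlang::abort("Soil texture fractions must sum to 100 (+/- 0.5)",
                 class = "tillerscope_soil_error")
  }
  dplyr::mutate(
    tibble::as_tibble(soil),
    no3_kg = nutrient_mass(.data$no3_conc, .data$bulk_density, consts$no3_depth),
    nh4_kg = nutrient_mass(.data$nh4_conc, .data$bulk_density, consts$nh4_depth),
    p_kg = nutrient_mass(.data$p_conc, .data$bulk_density, consts$p_depth)
  )
}

#' Derive the full covariate set for each observation
#'
#' Assembles, for every observation row, the predictor set used by the
#' candidate models: cumulative growing degree days, photothermal quotient,
#' temperature means and amplitude, cumulative moisture (from one month
#' pre-sowing) and vapour pressure deficit — all over the window from sowing
#' to the observation date — plus the plant-density class and the site-year
#' soil variables with nutrient concentrations converted to kg ha^-1.
#'
#' @param observations Tibble with one row per plot measurement: `site_year`,
#'   `season`, `genotype`, `stage`, `sow_date`, `obs_date`, `target_pd`,
#'   `observed_pd`, `tiller_density`.
#' @param weather Daily weather tibble (`site_year`, `date`, `t_min`,
#'   `t_max`, `radiation`, `vpd`, `precip`, optionally `irrigation`)
#'   covering at least `sow_date - pre_sow_window` to the latest
#'   observation for every site-year.
#' @param soil One row per site-year: `site_year`, `ph`, `om`, `no3_conc`,
#'   `nh4_conc`, `p_conc`, `cec`, `sand`, `silt`, `clay`, `bulk_density`.
#' @param consts A [tiller_constants()] object.
#' @return A tibble with one row per observation carrying the observation
#'   identifiers, the derived covariates (`gdd`, `ptq`, `t_min_mean`,
#'   `t_max_mean`, `t_amp_mean`, `cm`, `vpd_cum`, `pd_class`) and the soil
#'   fields (`ph`, `om`, `no3_kg`, `nh4_kg`, `p_kg`, `cec`, `sand`, `silt`,
#'   `clay`).
#' @export
derive_covariates <- function(observations, weather, soil,
                              consts = tiller_constants()) {
  obs <- tibble::as_tibble(observations)
  req <- c("site_year", "season", "genotype", "stage", "sow_date", "obs_date",
           "observed_pd", "tiller_density")
  missing <- setdiff(req, names(obs))
  if (length(missing) > 0) {
    rlang::abort(paste0("Observations table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tillerscope_schema_error")
  }
  if (any(obs$obs_date <= obs$sow_date)) {
    bad <- which(obs$obs_date <= obs$sow_date)[1]
    rlang::abort(
      sprintf("Observation %d (%s) is not after its sowing date",
              bad, obs$site_year[bad]),
      class = "tillerscope_observation_error"
    )
  }
  soil <- prepare_soil(soil, consts)
  wsplit <- split(tibble::as_tibble(weather), weather$site_year)

  # Per-site cumulative-sum tables make each observation an O(1) lookup;
  # results agree with the per-window operations above (same arithmetic,
  # accumulated once per site instead of once per observation).
  site_index <- lapply(wsplit, function(w) {
    w <- w[order(w$date), , drop = FALSE]
    full <- seq(min(w$date), max(w$date), by = "day")
    hit <- match(full, w$date)
    if (anyNA(hit)) {
      rlang::abort(
        sprintf("Missing weather for %s on %s", w$site_year[1],
                format(full[which(is.na(hit))[1]])),
        class = "tillerscope_missing_day_error"
      )
    }
    w <- w[hit, , drop = FALSE]
    irr <- if ("irrigation" %in% names(w)) w$irrigation else 0
    list(
      date0 = w$date[1], daten = w$date[nrow(w)],
      cg = cumsum(daily_gdd(w$t_min, w$t_max, consts)),
      cv = cumsum(w$vpd),
      cmoist = cumsum(w$precip + irr),
      ctmin = cumsum(w$t_min), ctmax = cumsum(w$t_max),
      ctmean = cumsum((w$t_min + w$t_max) / 2),
      crad = cumsum(w$radiation)
    )
  })
  win_sum <- function(cs, i0, i1) cs[i1] - if (i0 > 1) cs[i0 - 1] else 0

  rows <- purrr::pmap(
    list(obs$site_year, obs$sow_date, obs$obs_date),
    function(sy, sow, od) {
      s <- site_index[[as.character(sy)]]
      if (is.null(s)) {
        rlang::abort(sprintf("No weather series for site-year %s", sy),
                     class = "tillerscope_missing_day_error")
      }
      from_cm <- sow - consts$pre_sow_window
      if (from_cm < s$date0 || od > s$daten) {
        miss <- if (from_cm < s$date0) from_cm else s$daten + 1
        rlang::abort(
          sprintf("Site-year %s: missing weather on %s (window %s to %s)",
                  sy, format(miss), format(from_cm), format(od)),
          class = "tillerscope_missing_day_error"
        )
      }
      i0 <- as.integer(sow - s$date0) + 1L
      i1 <- as.integer(od - s$date0) + 1L
      icm <- as.integer(from_cm - s$date0) + 1L
      n <- i1 - i0 + 1L
      t_mean_bar <- win_sum(s$ctmean, i0, i1) / n
      denom <- t_mean_bar - consts$t_base
      if (denom <= 0) {
        rlang::abort(
          sprintf(paste0("Site-year %s: degenerate photothermal quotient ",
                         "(window mean temperature %.2f degC at or below ",
                         "the %g degC base)"),
                  sy, t_mean_bar, consts$t_base),
          class = "tillerscope_degenerate_period_error"
        )
      }
      tmin_bar <- win_sum(s$ctmin, i0, i1) / n
      tmax_bar <- win_sum(s$ctmax, i0, i1) / n
      tibble::tibble(
        gdd = win_sum(s$cg, i0, i1),
        ptq = (win_sum(s$crad, i0, i1) / n) / denom,
        t_min_mean = tmin_bar,
        t_max_mean = tmax_bar,
        t_amp_mean = tmax_bar - tmin_bar,
        cm = win_sum(s$cmoist, icm, i1),
        vpd_cum = win_sum(s$cv, i0, i1)
      )
    }
  )

  out <- dplyr::bind_cols(
    obs,
    dplyr::bind_rows(rows)
  )
  out$pd_class <- classify_plant_density(out$observed_pd)
  out$genotype <- factor(out$genotype)
  soil_cols <- c("site_year", "ph", "om", "no3_kg", "nh4_kg", "p_kg",
                 "cec", "sand", "silt", "clay")
  dplyr::left_join(out, soil[, soil_cols], by = "site_year")
}
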