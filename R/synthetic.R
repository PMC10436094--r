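#' Configuration for the synthetic site-year generator
#'
#' Describes a multi-season, multi-site field campaign: how many seasons and
#' sites, the plot structure (plant-density targets, genotypes, development
#' stages with fixed day offsets after sowing, replicates), a seasonal
#' sinusoid weather model, and per-site soil sampling envelopes. Defaults
#' emulate the 17-site-year, three-season Kansas campaign the pipeline is
#' designed around: targets of 25000/42000/60000 plants per hectare, two
#' genotypes, five observation stages from fifth leaf to maturity, and soil
#' chemistry drawn from the observed site characterisation ranges (pH
#' 5.2-7.9, organic matter 1.0-6.2 %, nitrate 1.8-43.5 mg/kg, Mehlich
#' phosphorus 13.3-118 mg/kg).
#'
#' @param n_seasons Number of seasons (calendar years, consecutive).
#' @param first_season First season year.
#' @param sites_per_season Integer vector (recycled to `n_seasons`) of sites
#'   per season; the default `c(6, 6, 5)` gives 17 site-years.
#' @param n_reps Replicate plots per site-year x density x genotype x stage.
#' @param genotypes Genotype labels.
#' @param pd_noise_sd SD (plants/ha) of realised around target plant density.
#' @param stage_offsets Named vector of days after sowing per stage.
#' @param sow_doy_mean,sow_doy_sd Sowing day-of-year distribution.
#' @param weather List of weather-model parameters (seasonal mean/amplitude
#'   and phase of mean temperature, daily noise, thermal amplitude, solar
#'   radiation sinusoid, VPD-temperature link, precipitation frequency and
#'   scale, irrigation).
#' @param soil List of per-field uniform sampling ranges, each `c(min, max)`.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_seasons = 3,
                             first_season = 2019,
                             sites_per_season = c(6, 6, 5),
                             n_reps = 3,
                             genotypes = c("G1", "G2"),
                             pd_noise_sd = 3000,
                             stage_offsets = c(V5 = 30, V10 = 50, V16 = 65,
                                               R3 = 85, R6 = 120),
                             sow_doy_mean = 128,
                             sow_doy_sd = 8,
                             weather = list(
                               temp_mean = 15, temp_amplitude = 11,
                               temp_phase_doy = 130, site_offset_sd = 1.2,
                               daily_sd = 2.2,
                               amp_mean = 12, amp_sd = 2,
                               rad_mean = 17, rad_amplitude = 7, rad_sd = 3,
                               vpd_slope = 0.085, vpd_base = 8, vpd_sd = 0.15,
                               p_wet = 0.25, rain_shape = 0.9, rain_scale = 9,
                               p_irrigated = 0.5, irrigation_mm = 5,
                               irrigation_every = 5
                             ),
                             soil = list(
                               ph = c(5.2, 7.9), om = c(1.0, 6.2),
                               no3_conc = c(1.8, 43.5), nh4_conc = c(0, 36.4),
                               p_conc = c(13.3, 118), cec = c(5.9, 25.6),
                               sand = c(15, 55), clay = c(10, 30),
                               bulk_density = c(1.1, 1.5)
                             )) {
  stopifnot(n_seasons >= 1, n_reps >= 1, pd_noise_sd >= 0,
            all(stage_offsets > 0))
  structure(
    list(n_seasons = n_seasons, first_season = first_season,
         sites_per_season = rep_len(sites_per_season, n_seasons),
         n_reps = n_reps, genotypes = genotypes, pd_noise_sd = pd_noise_sd,
         stage_offsets = stage_offsets, sow_doy_mean = sow_doy_mean,
         sow_doy_sd = sow_doy_sd, weather = weather, soil = soil),
    class = "generator_config"
  )
}

# A logit-scale effect of one covariate. Parameters may be scalars or named
# vectors over the density classes A/B/C; `seasons` restricts the effect to
# a subset of years (NULL = all).
logit_effect <- function(covariate, type = c("sigmoid", "band", "class_offset"),
                         seasons = NULL, ...) {
  type <- match.arg(type)
  structure(list(covariate = covariate, type = type, seasons = seasons,
                 params = list(...)),
            class = "logit_effect")
}

param_by_class <- function(p, cls) {
  if (is.null(p)) return(rep(0, length(cls)))
  if (length(p) == 1 && is.null(names(p))) return(rep(p, length(cls)))
  unname(p[as.character(cls)])
}

eval_effect <- function(effect, x, pd_class, season) {
  pp <- effect$params
  out <- switch(
    effect$type,
    sigmoid = param_by_class(pp$height, pd_class) *
      (stats::plogis((x - param_by_class(pp$location, pd_class)) /
                       param_by_class(pp$scale, pd_class)) -
         if (isTRUE(pp$centered)) 0.5 else 0),
    band = param_by_class(pp$rise_height, pd_class) *
      stats::plogis((x - param_by_class(pp$rise_location, pd_class)) /
                      param_by_class(pp$rise_scale, pd_class)) -
      param_by_class(pp$fall_height, pd_class) *
      stats::plogis((x - param_by_class(pp$fall_location, pd_class)) /
                      pmax(param_by_class(pp$fall_scale, pd_class), 1e-9)),
    class_offset = param_by_class(pp$offsets, pd_class)
  )
  if (!is.null(effect$seasons)) out <- out * as.numeric(season %in% effect$seasons)
  out
}

#' Define a ground-truth response for the generator
#'
#' The truth is a logistic model of the probability of attaining the maximum
#' tiller density: an intercept plus additive logit-scale effects of derived
#' covariates (sigmoidal rises, rise-and-fall bands, or per-density-class
#' offsets), plus an observation noise model. Because effects live on the
#' logit scale the implied probability is always inside (0, 1).
#'
#' @param intercept Logit-scale intercept.
#' @param effects List of effects built with internal constructor
#'   `logit_effect()`; exposed via [scenario_presets()].
#' @param noise One of `"betabinom"` (beta-binomial with intraclass
#'   correlation `rho`), `"gaussian"` (additive on the density scale with
#'   `sd`), or `"none"` (densities equal truth exactly).
#' @param rho Beta-binomial intraclass correlation.
#' @param sd Gaussian noise SD (tillers/ha).
#' @return A list of class `true_response`.
#' @export
true_response <- function(intercept, effects = list(),
                          noise = c("betabinom", "gaussian", "none"),
                          rho = 0.02, sd = 8000) {
  noise <- match.arg(noise)
  stopifnot(rho >= 0, rho < 1, sd >= 0)
  structure(list(intercept = intercept, effects = effects, noise = noise,
                 rho = rho, sd = sd),
            class = "true_response")
}

#' Evaluate the ground-truth probability at given covariates
#'
#' @param truth A [true_response()].
#' @param data Tibble with the effect covariates plus `pd_class` and
#'   `season`.
#' @return Numeric vector of true probabilities in (0, 1).
#' @export
true_probability <- function(truth, data) {
  eta <- rep(truth$intercept, nrow(data))
  for (ef in truth$effects) {
    x <- if (ef$type == "class_offset") rep(0, nrow(data))
         else data[[ef$covariate]]
    if (is.null(x)) {
      rlang::abort(sprintf("Truth covariate '%s' missing from data",
                           ef$covariate),
                   class = "tillerscope_truth_error")
    }
    eta <- eta + eval_effect(ef, x, data$pd_class, data$season)
  }
  stats::plogis(eta)
}

#' Named scenario presets for the generator
#'
#' Four ground-truth scenarios exercising different pipeline stages:
#' \describe{
#'   \item{null}{Constant probability (no covariate effects) — null-signal
#'     recovery.}
#'   \item{gdd_step}{A single sharp thermal-time threshold: the probability
#'     rises through 0.50 exactly at 200 degC day — function and threshold
#'     recovery.}
#'   \item{exm}{An environment-by-management truth: saturating thermal and
#'     photothermal effects, a vapour-pressure-deficit band whose upper
#'     limit tightens at higher plant densities, soil nitrate and
#'     phosphorus effects, and density-class offsets — candidate ranking.}
#'   \item{season_shift}{A soil-phosphorus effect present in the first two
#'     seasons only — out-of-season error attribution.}
#' }
#'
#' @return Named list; each element has `config` (a [generator_config()])
#'   and `truth` (a [true_response()]).
#' @export
scenario_presets <- function() {
  base_cfg <- generator_config()
  list(
    null = list(
      config = base_cfg,
      truth = true_response(intercept = stats::qlogis(0.096))
    ),
    gdd_step = list(
      config = base_cfg,
      truth = true_response(
        intercept = -3,
        effects = list(
          logit_effect("gdd", "sigmoid", height = 6, location = 200,
                       scale = 15)
        )
      )
    ),
    exm = list(
      config = base_cfg,
      truth = true_response(
        intercept = -5.7,
        effects = list(
          logit_effect("gdd", "sigmoid", height = 1.4, location = 200,
                       scale = 40),
          logit_effect("ptq", "sigmoid", height = 0.6, location = 2.0,
                       scale = 0.25),
          logit_effect("vpd_cum", "band",
                       rise_height = 0.9, rise_location = 30, rise_scale = 10,
                       fall_height = c(A = 0, B = 0.9, C = 1.3),
                       fall_location = c(A = 1e6, B = 200, C = 150),
                       fall_scale = 25),
          logit_effect("t_max_mean", "sigmoid", height = 0.6,
                       location = c(A = 22, B = 22, C = 26), scale = 1.2),
          logit_effect("no3_kg", "band",
                       rise_height = 0.3, rise_location = 50, rise_scale = 20,
                       fall_height = c(A = 0.5, B = 0, C = 0.6),
                       fall_location = c(A = 200, B = 1e6, C = 230),
                       fall_scale = 30),
          logit_effect("p_kg", "sigmoid",
                       height = c(A = 0.7, B = 0.2, C = 0.4),
                       location = 100, scale = 15),
          logit_effect("pd_class", "class_offset",
                       offsets = c(A = 0.5, B = 0, C = -0.5))
        )
      )
    ),
    season_shift = list(
      config = base_cfg,
      truth = true_response(
        intercept = -2.8,
        effects = list(
          logit_effect("gdd", "sigmoid", height = 0.6, location = 200,
                       scale = 60),
          # soil-phosphorus effect present in the first two seasons only;
          # centred at the median areal phosphorus mass so the shifted
          # signal lives in the term, not in the absorbed mean
          logit_effect("p_kg", "sigmoid", height = 3.0, location = 145,
                       scale = 30, centered = TRUE, seasons = c(2019, 2020))
        )
      )
    )
  )
}

# Daily weather series for one site-year.
simulate_weather <- function(site_year, dates, wp, irrigated, sow_date) {
  doy <- as.integer(format(dates, "%j"))
  seasonal <- wp$temp_mean +
    wp$temp_amplitude * sin(2 * pi * (doy - wp$temp_phase_doy) / 365)
  site_off <- stats::rnorm(1, 0, wp$site_offset_sd)
  t_mean <- seasonal + site_off + stats::rnorm(length(doy), 0, wp$daily_sd)
  amp <- pmax(3, stats::rnorm(length(doy), wp$amp_mean, wp$amp_sd))
  t_min <- t_mean - amp / 2
  t_max <- t_mean + amp / 2
  radiation <- pmax(1, wp$rad_mean +
                      wp$rad_amplitude * sin(2 * pi * (doy - wp$temp_phase_doy) / 365) +
                      stats::rnorm(length(doy), 0, wp$rad_sd))
  vpd <- pmax(0.05, wp$vpd_slope * (t_max - wp$vpd_base) +
                stats::rnorm(length(doy), 0, wp$vpd_sd))
  precip <- stats::rbinom(length(doy), 1, wp$p_wet) *
    stats::rgamma(length(doy), shape = wp$rain_shape, scale = wp$rain_scale)
  irrigation <- rep(0, length(doy))
  if (irrigated) {
    after_sow <- as.integer(dates - sow_date)
    irrigation[after_sow >= 0 & after_sow %% wp$irrigation_every == 0] <-
      wp$irrigation_mm
  }
  tibble::tibble(site_year = site_year, date = dates,
                 t_min = round(t_min, 2), t_max = round(t_max, 2),
                 radiation = round(radiation, 2), vpd = round(vpd, 3),
                 precip = round(precip, 2), irrigation = irrigation)
}

#' Generate a synthetic multi-season field dataset with known truth
#'
#' Produces the three tables the covariate module consumes (daily weather,
#' soil characterisation, plot observations), with tiller densities drawn
#' from a known ground-truth response evaluated at each observation's
#' derived covariates. Fully seeded and reproducible; the returned truth
#' manifest records the generator parameters, every effect function and the
#' per-observation true probabilities, so recovery can be tested.
#'
#' @param config A [generator_config()].
#' @param truth A [true_response()]; defaults to the `exm` preset.
#' @param seed Integer seed controlling every draw.
#' @param consts A [tiller_constants()] used to derive covariates.
#' @return List with `weather`, `soil`, `observations`, `covariates` (the
#'   derived covariate table with observed densities), and `truth_manifest`
#'   (generator/truth parameters, per-observation `p_true`, effect
#'   locations).
#' @export
generate_tiller_data <- function(config = generator_config(),
                                 truth = scenario_presets()$exm$truth,
                                 seed = 1,
                                 consts = tiller_constants()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "true_response"))
  withr::with_seed(seed, {
    seasons <- config$first_season + seq_len(config$n_seasons) - 1
    wp <- config$weather
    max_offset <- max(config$stage_offsets)

    weather_l <- list(); soil_l <- list(); obs_l <- list()
    for (si in seq_along(seasons)) {
      year <- seasons[si]
      for (k in seq_len(config$sites_per_season[si])) {
        sy <- sprintf("site%02d_%d", k, year)
        sow_doy <- round(stats::rnorm(1, config$sow_doy_mean, config$sow_doy_sd))
        sow_date <- as.Date(sprintf("%d-01-01", year)) + sow_doy - 1
        dates <- seq(sow_date - consts$pre_sow_window - 5,
                     sow_date + max_offset + 2, by = "day")
        irrigated <- stats::runif(1) < wp$p_irrigated
        weather_l[[sy]] <- simulate_weather(sy, dates, wp, irrigated, sow_date)

        sr <- config$soil
        runi <- function(r) stats::runif(1, r[1], r[2])
        sand <- runi(sr$sand); clay <- runi(sr$clay)
        soil_l[[sy]] <- tibble::tibble(
          site_year = sy, ph = round(runi(sr$ph), 2),
          om = round(runi(sr$om), 2),
          no3_conc = round(runi(sr$no3_conc), 2),
          nh4_conc = round(runi(sr$nh4_conc), 2),
          p_conc = round(runi(sr$p_conc), 2),
          cec = round(runi(sr$cec), 2),
          sand = round(sand, 1), clay = round(clay, 1),
          silt = round(100 - sand - clay, 1),
          bulk_density = round(runi(sr$bulk_density), 3)
        )

        grid <- tidyr::expand_grid(
          target_pd = unname(PD_TARGETS),
          genotype = config$genotypes,
          stage = names(config$stage_offsets),
          rep = seq_len(config$n_reps)
        )
        grid$observed_pd <- pmax(5000, round(grid$target_pd +
          stats::rnorm(nrow(grid), 0, config$pd_noise_sd)))
        obs_l[[sy]] <- tibble::tibble(
          site_year = sy, season = year, genotype = grid$genotype,
          stage = grid$stage, sow_date = sow_date,
          obs_date = sow_date + config$stage_offsets[grid$stage],
          target_pd = grid$target_pd, observed_pd = grid$observed_pd,
          tiller_density = 0
        )
      }
    }
    weather <- dplyr::bind_rows(weather_l)
    soil <- dplyr::bind_rows(soil_l)
    observations <- dplyr::bind_rows(obs_l)

    covariates <- derive_covariates(observations, weather, soil, consts)
    p_true <- true_probability(truth, covariates)

    y <- switch(
      truth$noise,
      none = p_true * consts$y_max,
      gaussian = pmin(pmax(p_true * consts$y_max +
                             stats::rnorm(length(p_true), 0, truth$sd), 0),
                      consts$y_max),
      betabinom = {
        if (truth$rho == 0) {
          stats::rbinom(length(p_true), consts$y_max, p_true)
        } else {
          a <- p_true * (1 - truth$rho) / truth$rho
          b <- (1 - p_true) * (1 - truth$rho) / truth$rho
          q <- stats::rbeta(length(p_true), a, b)
          stats::rbinom(length(p_true), consts$y_max, q)
        }
      }
    )
    observations$tiller_density <- as.numeric(y)
    covariates$tiller_density <- as.numeric(y)

    locations <- purrr::map_dfr(truth$effects, function(ef) {
      if (ef$type == "class_offset") return(tibble::tibble())
      loc <- ef$params$location %||% ef$params$rise_location
      tibble::tibble(covariate = ef$covariate, type = ef$type,
                     location = list(loc))
    })

    list(
      weather = weather, soil = soil, observations = observations,
      covariates = covariates,
      truth_manifest = list(
        seed = seed, truth = truth, config = config,
        p_true = tibble::tibble(row = seq_len(nrow(covariates)),
                                p_true = p_true),
        effect_locations = locations
      )
    )
  })
}
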