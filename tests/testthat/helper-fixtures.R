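# Small deterministic fixtures shared across test files.

# Constant-weather series for one site: every day identical, so window
# aggregates have closed forms.
const_weather <- function(site_year = "siteA_2019",
                          start = as.Date("2019-04-01"), n_days = 200,
                          t_min = 15, t_max = 25, radiation = 20, vpd = 1.2,
                          precip = 2, irrigation = 0) {
  tibble::tibble(
    site_year = site_year,
    date = seq(start, by = "day", length.out = n_days),
    t_min = t_min, t_max = t_max, radiation = radiation, vpd = vpd,
    precip = precip, irrigation = irrigation
  )
}

fixture_soil <- function(site_year = "siteA_2019", no3 = 20, nh4 = 5,
                         p = 50, bd = 1.3) {
  tibble::tibble(
    site_year = site_year, ph = 6.5, om = 2.5, no3_conc = no3,
    nh4_conc = nh4, p_conc = p, cec = 18, sand = 30, silt = 45, clay = 25,
    bulk_density = bd
  )
}

fixture_observations <- function(site_year = "siteA_2019",
                                 sow = as.Date("2019-05-10"),
                                 offsets = c(30, 60, 120),
                                 stages = c("V5", "V10", "R6"),
                                 observed_pd = 41000,
                                 tiller_density = 30000) {
  tibble::tibble(
    site_year = site_year, season = 2019, genotype = "G1",
    stage = stages, sow_date = sow, obs_date = sow + offsets,
    target_pd = 42000, observed_pd = observed_pd,
    tiller_density = tiller_density
  )
}

# One modest simulated dataset shared by several test files (built once per
# test run).
.shared <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- generate_tiller_data(generator_config(n_reps = 1),
                                        seed = 42)
  }
  .shared$sim
}

# A fast-fitting single-smooth spec used where candidate structure is not
# under test.
gdd_only_spec <- function() model_spec("gdd-only", smooths = "gdd")
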