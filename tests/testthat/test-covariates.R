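test_that("daily degree days respect the base, the cap and the floor", {
  expect_equal(daily_gdd(20, 30), 15)
  expect_equal(daily_gdd(32, 38), 20)  # mean 35 capped to 30
  expect_equal(daily_gdd(4, 12), 0)    # mean 8 below base
  # vectorised, and always within [0, cap - base]
  set.seed(11)
  tmin <- runif(500, -15, 35)
  tmax <- tmin + runif(500, 0, 20)
  g <- daily_gdd(tmin, tmax)
  expect_true(all(g >= 0 & g <= 20))
  expect_error(daily_gdd(20, 10), class = "tillerscope_weather_error")
})

test_that("the cap variant caps t_max before averaging", {
  consts <- tiller_constants(gdd_cap = "tmax")
  # t_min 20, t_max 38: capped t_max 30, mean 25 -> 15
  expect_equal(daily_gdd(20, 38, consts), 15)
  # mean-variant would cap the mean at 30 -> 19
  expect_equal(daily_gdd(20, 38), 19)
})

test_that("cumulative degree days are additive over the window", {
  w <- const_weather(t_min = 20, t_max = 30)  # daily GDD 15
  sow <- w$date[5]
  expect_equal(cumulative_gdd(w, sow, sow + 9), 150)  # 10 days x 15
  expect_equal(cumulative_gdd(w, sow, sow), 0)        # nothing accrued yet
  # mixed series agrees with a brute-force day-by-day sum
  set.seed(7)
  w2 <- const_weather()
  w2$t_min <- runif(nrow(w2), 2, 18)
  w2$t_max <- w2$t_min + runif(nrow(w2), 2, 15)
  brute <- sum(vapply(which(w2$date >= sow & w2$date <= sow + 40),
                      function(i) daily_gdd(w2$t_min[i], w2$t_max[i]),
                      numeric(1)))
  expect_equal(cumulative_gdd(w2, sow, sow + 40), brute)
  # monotone non-decreasing in window length
  lens <- seq(5, 60, by = 5)
  vals <- vapply(lens, function(L) cumulative_gdd(w2, sow, sow + L),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("missing weather days abort naming the first missing date", {
  w <- const_weather()
  gap <- w$date[50]
  w <- w[w$date != gap, ]
  expect_error(cumulative_gdd(w, w$date[40], w$date[60]),
               regexp = format(gap),
               class = "tillerscope_missing_day_error")
})

test_that("photothermal quotient is radiation over thermal-time rate", {
  w <- const_weather(t_min = 16, t_max = 26, radiation = 22)  # mean temp 21
  sow <- w$date[10]
  expect_equal(photothermal_quotient(w, sow, sow + 29), 2.0)
  # degenerate period: mean temperature at the base
  w0 <- const_weather(t_min = 5, t_max = 15)  # mean exactly 10
  expect_error(photothermal_quotient(w0, sow, sow + 29),
               class = "tillerscope_degenerate_period_error")
  # varying series agrees with the hand-computed quotient
  set.seed(3)
  w2 <- const_weather()
  w2$t_min <- runif(nrow(w2), 8, 18)
  w2$t_max <- w2$t_min + 10
  w2$radiation <- runif(nrow(w2), 12, 28)
  win <- w2$date >= sow & w2$date <= sow + 29
  expected <- mean(w2$radiation[win]) /
    (mean((w2$t_min[win] + w2$t_max[win]) / 2) - 10)
  expect_equal(photothermal_quotient(w2, sow, sow + 29), expected)
})

test_that("cumulative VPD, moisture and temperature means have closed forms", {
  w <- const_weather(vpd = 1.2, precip = 2, irrigation = 0,
                     t_min = 10, t_max = 24)
  sow <- w$date[40]
  expect_equal(cumulative_vpd(w, sow, sow + 4), 6.0)  # 5 x 1.2
  # dryland: moisture is the precipitation sum over the extended window
  expect_equal(cumulative_moisture(w, sow, sow + 9),
               2 * (30 + 10))  # 30 pre-sow days + sow..sow+9
  tm <- temp_means(w, sow, sow + 9)
  expect_equal(tm$t_amp_mean, 14)
  expect_equal(tm$t_min_mean, 10)
  expect_lte(tm$t_min_mean, tm$t_max_mean)
  # irrigation adds to the moisture sum
  wi <- const_weather(precip = 2, irrigation = 3)
  expect_equal(cumulative_moisture(wi, sow, sow + 9), 5 * 40)
})

test_that("nutrient mass conversion is dimensionally correct and linear", {
  expect_equal(nutrient_mass(26.8, 1.3, 60), 209.04)
  expect_equal(nutrient_mass(0, 1.3, 60), 0)
  expect_equal(nutrient_mass(26.8, 1.3, 120), 2 * nutrient_mass(26.8, 1.3, 60))
  expect_equal(nutrient_mass(53.6, 1.3, 60), 2 * nutrient_mass(26.8, 1.3, 60))
  # round trip back to a concentration
  mass <- nutrient_mass(17.3, 1.42, 15)
  expect_equal(mass / (1.42 * 0.15 * 10), 17.3, tolerance = 1e-9)
  expect_error(nutrient_mass(10, 0, 60), class = "tillerscope_soil_error")
  expect_error(nutrient_mass(10, 1.3, -5), class = "tillerscope_soil_error")
})

test_that("plant-density classification is nearest-target with low ties", {
  expect_equal(as.character(classify_plant_density(30000)), "A")
  expect_equal(as.character(classify_plant_density(41295)), "B")
  expect_equal(as.character(classify_plant_density(33500)), "A")  # tie -> lower
  expect_equal(as.character(classify_plant_density(51000)), "B")  # tie -> lower
  expect_equal(as.character(classify_plant_density(90000)), "C")
  expect_error(classify_plant_density(0),
               class = "tillerscope_observation_error")
  # total and idempotent over a positive grid
  grid <- seq(1000, 120000, by = 777)
  cls <- classify_plant_density(grid)
  expect_false(anyNA(cls))
  centers <- c(A = 25000, B = 42000, C = 60000)[as.character(cls)]
  expect_identical(classify_plant_density(unname(centers)), cls)
})

test_that("derive_covariates matches the component operations field by field", {
  w <- const_weather()
  set.seed(5)
  w$t_min <- runif(nrow(w), 8, 16)
  w$t_max <- w$t_min + runif(nrow(w), 4, 14)
  w$vpd <- runif(nrow(w), 0.4, 2)
  w$precip <- rbinom(nrow(w), 1, 0.3) * runif(nrow(w), 0, 20)
  obs <- fixture_observations()
  soil <- fixture_soil()
  cv <- derive_covariates(obs, w, soil)
  for (i in seq_len(nrow(obs))) {
    expect_equal(cv$gdd[i], cumulative_gdd(w, obs$sow_date[i], obs$obs_date[i]))
    expect_equal(cv$ptq[i],
                 photothermal_quotient(w, obs$sow_date[i], obs$obs_date[i]))
    expect_equal(cv$vpd_cum[i],
                 cumulative_vpd(w, obs$sow_date[i], obs$obs_date[i]))
    expect_equal(cv$cm[i],
                 cumulative_moisture(w, obs$sow_date[i], obs$obs_date[i]))
    tm <- temp_means(w, obs$sow_date[i], obs$obs_date[i])
    expect_equal(cv$t_amp_mean[i], tm$t_amp_mean)
  }
  # soil areal masses carried through
  expect_equal(cv$no3_kg[1], nutrient_mass(20, 1.3, 60))
  expect_equal(cv$p_kg[1], nutrient_mass(50, 1.3, 15))
  # cumulative covariates non-decreasing with later stages
  expect_true(all(diff(cv$gdd) >= 0))
  expect_true(all(diff(cv$vpd_cum) >= 0))
  expect_true(all(diff(cv$cm) >= 0))
})

test_that("derive_covariates rejects degenerate and incomplete inputs", {
  w <- const_weather()
  soil <- fixture_soil()
  obs <- fixture_observations()
  obs$obs_date[1] <- obs$sow_date[1]  # observation at sowing
  expect_error(derive_covariates(obs, w, soil),
               class = "tillerscope_observation_error")
  obs2 <- fixture_observations()
  w2 <- w[w$date != obs2$sow_date[1] + 10, ]  # puncture the series
  err <- expect_error(derive_covariates(obs2, w2, soil),
                      class = "tillerscope_missing_day_error")
  expect_match(conditionMessage(err), format(obs2$sow_date[1] + 10))
  # unknown site-year
  obs3 <- fixture_observations(site_year = "nowhere_2019")
  expect_error(derive_covariates(obs3, w, soil),
               class = "tillerscope_missing_day_error")
  # soil texture must close to 100
  soil_bad <- fixture_soil()
  soil_bad$sand <- 60
  expect_error(derive_covariates(fixture_observations(), w, soil_bad),
               class = "tillerscope_soil_error")
})
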