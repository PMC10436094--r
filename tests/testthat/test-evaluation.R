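test_that("cross-season splits are stratified, seeded and reproducible", {
  sim <- shared_sim()
  cov <- sim$covariates
  s1 <- cross_season_split(cov, seed = 3)
  s2 <- cross_season_split(cov, seed = 3)
  expect_identical(s1, s2)
  expect_equal(length(s1$test) / nrow(cov), 0.2, tolerance = 0.02)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_len(nrow(cov)))
  expect_error(cross_season_split(cov, fraction = 1.2),
               class = "tillerscope_split_error")
})

test_that("every site-year keeps a similar test share across seeds", {
  # uneven site-year sizes so stratification actually has work to do
  df <- tibble::tibble(
    site_year = rep(c("a", "b", "c"), times = c(30, 45, 60))
  )
  for (seed in 1:100) {
    sp <- cross_season_split(df, seed = seed)
    share <- prop.table(table(df$site_year[sp$test]))
    per_site <- table(df$site_year[sp$test]) / table(df$site_year)
    expect_true(all(abs(per_site - 0.2) <= 0.10))
  }
})

test_that("out-of-season splits partition the data by season", {
  sim <- shared_sim()
  cov <- sim$covariates
  plans <- out_of_season_splits(cov)
  expect_length(plans, 3)
  expect_setequal(unlist(lapply(plans, `[[`, "test")), seq_len(nrow(cov)))
  for (p in plans) {
    expect_length(intersect(p$train, p$test), 0)
    expect_true(all(cov$season[p$test] == p$held_out_season))
    expect_true(all(cov$season[p$train] != p$held_out_season))
  }
  one_season <- cov[cov$season == 2019, ]
  expect_error(out_of_season_splits(one_season),
               class = "tillerscope_split_error")
})

test_that("MAE and MBE match their definitions", {
  m <- mae_mbe(c(3, -5), c(0, 0))
  expect_equal(m$mae, 4)
  expect_equal(m$mbe, -1)
  expect_equal(mae_mbe(1:5, 1:5), tibble::tibble(mae = 0, mbe = 0))
  set.seed(2)
  pred <- rnorm(50, 30000, 5000); obs <- rnorm(50, 30000, 5000)
  m2 <- mae_mbe(pred, obs)
  expect_equal(m2$mae, sum(abs(pred - obs)) / 50)
  expect_equal(m2$mbe, sum(pred - obs) / 50)
  expect_gte(m2$mae, abs(m2$mbe))
  expect_error(mae_mbe(numeric(), numeric()),
               class = "tillerscope_metric_error")
  expect_error(mae_mbe(1:3, 1:4), class = "tillerscope_metric_error")
})

test_that("candidate ranking orders by held-out MAE with stable ties", {
  sim <- shared_sim()
  cov <- sim$covariates
  split <- cross_season_split(cov, seed = 1)
  solo <- rank_candidates(cov, split,
                          registry = candidate_registry()["Temporal"])
  expect_equal(nrow(solo), 1)
  expect_true(solo$selected)
  # two copies of the same candidate tie and keep registry order
  reg2 <- candidate_registry()[c("Temporal", "Temporal")]
  names(reg2) <- c("first", "second")
  ev2 <- rank_candidates(cov, split, registry = reg2)
  expect_equal(ev2$mae[1], ev2$mae[2])
  expect_equal(ev2$candidate[ev2$rank == 1], "first")
  # order invariance apart from tie-breaking
  reg3 <- candidate_registry()[c("Temporal", "Soil")]
  evA <- rank_candidates(cov, split, registry = reg3)
  evB <- rank_candidates(cov, split, registry = rev(reg3))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(evA)[c("candidate", "mae")], candidate),
    dplyr::arrange(tibble::as_tibble(evB)[c("candidate", "mae")], candidate),
    ignore_attr = TRUE
  )
  ok <- is.finite(evA$mae)
  expect_true(all(evA$mae[ok] >= abs(evA$mbe[ok])))
})

test_that("attribution rows never report a lowest error above the full error", {
  sim <- shared_sim()
  at <- suppressWarnings(
    attribute_errors(sim$covariates, spec = gdd_only_spec())
  )
  expect_gt(nrow(at), 0)
  expect_true(all(at$lowest_error <= at$full_error + 1e-9))
  expect_true(all(at$lowest_error >= 0))
  # empty term marker only when nothing improved
  no_improve <- at$best_excluded_term == ""
  expect_equal(at$lowest_error[no_improve], at$full_error[no_improve])
  sm <- season_exclusion_mae(at)
  expect_true(all(c("(none)", "gdd") %in% sm$term))
  expect_equal(sum(sm$best), length(unique(at$held_out_season)))
})

test_that("site-years without a qualifying reference plot are skipped with warning", {
  sim <- shared_sim()
  cov <- sim$covariates
  drop_sy <- unique(cov$site_year[cov$season == min(cov$season)])[1]
  cov2 <- cov[!(cov$site_year == drop_sy & cov$stage == "R6" &
                  as.character(cov$pd_class) == "B"), ]
  expect_warning(
    attribute_errors(cov2, spec = gdd_only_spec(),
                     splits = out_of_season_splits(cov2)[1]),
    regexp = drop_sy
  )
})

test_that("attribution summaries count thresholds and failure shares", {
  toy <- tibble::tibble(
    held_out_season = c(2019, 2019, 2020, 2020, 2021),
    lowest_error = c(4000, 12000, 20000, 9000, 30000)
  )
  s <- summarize_attribution(toy, threshold = 10500)
  expect_equal(s$pct_below, 40)
  expect_equal(s$n_below, 2)
  expect_equal(s$n_total, 5)
  expect_equal(sum(s$failure_share$n), 3)
  expect_equal(
    s$failure_share$share_pct[s$failure_share$held_out_season == 2020] +
      s$failure_share$share_pct[s$failure_share$held_out_season == 2021] +
      s$failure_share$share_pct[s$failure_share$held_out_season == 2019],
    100
  )
})

test_that("held-out MAE of a well-specified fit approaches the noise floor", {
  # Gaussian observation noise of SD sigma: a perfectly recovered mean
  # leaves test MAE = sigma * sqrt(2/pi)
  sigma <- 8000
  truth <- true_response(
    intercept = -3,
    effects = list(tillerscope:::logit_effect("gdd", "sigmoid", height = 6,
                                              location = 200, scale = 60)),
    noise = "gaussian", sd = sigma
  )
  sim <- generate_tiller_data(generator_config(n_reps = 6), truth, seed = 8)
  cov <- sim$covariates
  split <- cross_season_split(cov, seed = 8)
  fit <- fit_tiller_model(cov[split$train, ], gdd_only_spec())
  pred <- predict(fit, cov[split$test, ])$tiller_density
  m <- mae_mbe(pred, cov$tiller_density[split$test])
  expect_equal(m$mae, sigma * sqrt(2 / pi), tolerance = 0.15)
})
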