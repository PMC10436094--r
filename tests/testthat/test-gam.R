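test_that("binomial response encoding scales by the maximum density", {
  r <- make_response(152842)
  expect_equal(r$successes, 152842)
  expect_equal(r$trials, 300000)
  expect_equal(r$proportion, 152842 / 300000)
  expect_equal(make_response(0)$proportion, 0)
  expect_equal(make_response(300000)$proportion, 1)
  err <- expect_error(make_response(300001),
                      class = "tillerscope_response_error")
  expect_match(conditionMessage(err), "maximum")
  expect_equal(make_response(100.4)$successes, 100)  # rounded to integer
})

test_that("the candidate registry matches the declared structures", {
  reg <- candidate_registry()
  expect_length(reg, 15)
  expect_setequal(reg[["Temporal"]]$smooths, c("gdd", "ptq"))
  expect_equal(reg[["Temporal"]]$by, "none")
  exm <- reg[["E x M"]]
  expect_setequal(exm$smooths, c("gdd", "ptq", "t_min_mean", "t_max_mean",
                                 "vpd_cum", "no3_kg", "p_kg"))
  expect_equal(exm$by, "pd_class")
  expect_equal(exm$factors, "pd_class")
  gm <- reg[["G + M"]]
  expect_equal(gm$smooths, "observed_pd")
  expect_equal(gm$factors, "genotype")
  expect_equal(gm$by, "none")
  expect_equal(reg[["G x E x M"]]$by, "genotype_pd_class")
  expect_equal(reg[["Soil"]]$by, "none")
  expect_error(model_spec("bad", smooths = "not_a_covariate"),
               class = "tillerscope_spec_error")
})

test_that("a constant response recovers its intercept with null smooths", {
  sim <- shared_sim()
  cov <- sim$covariates
  cov$tiller_density <- 0.1 * 300000  # exactly constant
  # zero residual variance leaves the quasi-likelihood dispersion undefined,
  # so the degenerate limit is checked under the fixed-scale binomial family
  consts <- tiller_constants(family = "binomial")
  fit <- suppressWarnings(  # degenerate zero-deviance data warns internally
    fit_tiller_model(cov, model_spec("flat", smooths = c("gdd", "p_kg")),
                     consts)
  )
  expect_equal(unname(fit$beta[1]), qlogis(0.1), tolerance = 1e-6)
  expect_lt(max(abs(fit$beta[-1])), 1e-6)
  expect_equal(predict(fit, cov[1:4, ])$probability, rep(0.1, 4),
               tolerance = 1e-6)
})

test_that("duplicating every observation leaves predictions essentially unchanged", {
  # the binomial likelihood is weight-invariant; REML smoothing selection is
  # weakly n-dependent, so predictions agree closely but not bitwise
  sim <- shared_sim()
  cov <- sim$covariates
  spec <- gdd_only_spec()
  f1 <- fit_tiller_model(cov, spec)
  f2 <- fit_tiller_model(dplyr::bind_rows(cov, cov), spec)
  p1 <- predict(f1, cov)$probability
  p2 <- predict(f2, cov)$probability
  expect_lt(max(abs(p1 - p2)), 0.02)
})

test_that("fitting is deterministic", {
  sim <- shared_sim()
  spec <- candidate_registry()[["Temporal"]]
  f1 <- fit_tiller_model(sim$covariates, spec)
  f2 <- fit_tiller_model(sim$covariates, spec)
  expect_lt(max(abs(predict(f1)$probability - predict(f2)$probability)), 1e-8)
})

test_that("zeroing coefficient blocks is idempotent and reduces to logistic(0)", {
  sim <- shared_sim()
  fit <- fit_tiller_model(sim$covariates, candidate_registry()[["E x M"]])
  z1 <- zero_term(fit, "vpd_cum")
  z2 <- zero_term(z1, "vpd_cum")
  expect_identical(z1$beta, z2$beta)
  expect_false(identical(fit$beta, z1$beta))
  # zeroing everything including the intercept gives probability 0.5 exactly
  zall <- fit
  for (tm in model_terms(fit, include_intercept = TRUE)) {
    zall <- zero_term(zall, tm)
  }
  pred <- predict(zall, sim$covariates[1:6, ])
  expect_identical(unique(pred$probability), 0.5)
  expect_identical(unique(pred$tiller_density), 150000)
  err <- expect_error(zero_term(fit, "moon_phase"),
                      class = "tillerscope_term_error")
  expect_match(conditionMessage(err), "vpd_cum")  # lists valid names
})

test_that("zeroing a term zeroes all of its by-class basis coefficients", {
  sim <- shared_sim()
  fit <- fit_tiller_model(sim$covariates, candidate_registry()[["E x M"]])
  z <- zero_term(fit, "gdd")
  idx <- fit$blocks[["gdd"]]
  expect_true(all(z$beta[idx] == 0))
  # three by-class smooths' worth of coefficients in the block
  expect_gte(length(idx), 3 * 5)
  # other blocks untouched
  other <- setdiff(seq_along(fit$beta), idx)
  expect_identical(z$beta[other], fit$beta[other])
})

test_that("prediction rejects unknown factor levels", {
  sim <- shared_sim()
  fit <- fit_tiller_model(sim$covariates, candidate_registry()[["G + M"]])
  nd <- sim$covariates[1:2, ]
  nd$genotype <- "G999"
  expect_error(predict(fit, nd), class = "tillerscope_level_error")
})

test_that("fitting errors when a density class is absent from training data", {
  sim <- shared_sim()
  cov <- sim$covariates[as.character(sim$covariates$pd_class) != "C", ]
  err <- expect_error(
    fit_tiller_model(cov, candidate_registry()[["E x M"]]),
    class = "tillerscope_level_error"
  )
  expect_match(conditionMessage(err), "C")
})

test_that("prediction intervals are seeded, bounded and collapse without noise", {
  sim <- shared_sim()
  fit <- fit_tiller_model(sim$covariates, gdd_only_spec())
  nd <- sim$covariates[c(10, 200, 400), ]
  pi1 <- prediction_interval(fit, nd, n_draws = 400, seed = 9)
  pi2 <- prediction_interval(fit, nd, n_draws = 400, seed = 9)
  expect_identical(pi1, pi2)
  expect_true(all(pi1$lower >= 0 & pi1$upper <= 300000))
  expect_true(all(pi1$lower <= pi1$tiller_density &
                    pi1$tiller_density <= pi1$upper))
  # degenerate covariance collapses the interval onto the point prediction
  fit0 <- fit
  fit0$Vp <- matrix(0, length(fit$beta), length(fit$beta))
  pi0 <- prediction_interval(fit0, nd, n_draws = 400, seed = 9)
  expect_equal(pi0$lower, pi0$tiller_density, tolerance = 1e-8)
  expect_equal(pi0$upper, pi0$tiller_density, tolerance = 1e-8)
  expect_error(prediction_interval(fit, nd, n_draws = 100),
               class = "tillerscope_interval_error")
  fit_nov <- fit
  fit_nov$Vp <- NULL
  expect_error(prediction_interval(fit_nov, nd, n_draws = 400),
               class = "tillerscope_interval_error")
})

test_that("tidy, glance and augment follow broom conventions", {
  sim <- shared_sim()
  fit <- fit_tiller_model(sim$covariates, candidate_registry()[["Temporal"]])
  td <- tidy(fit)
  expect_named(td, c("term", "edf", "ref_df", "statistic", "p_value"))
  expect_setequal(td$term, c("s(gdd)", "s(ptq)"))
  tp <- tidy(fit, type = "parametric")
  expect_true("(Intercept)" %in% tp$term)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, nrow(sim$covariates))
  expect_gt(gl$deviance_explained, 0)
  au <- augment(fit)
  expect_equal(nrow(au), nrow(sim$covariates))
  expect_true(all(au$.fitted_probability >= 0 & au$.fitted_probability <= 1))
})
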