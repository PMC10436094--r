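#' Encode tiller density as a binomial response
#'
#' Treats an observed tiller density as the number of "successes" out of the
#' assumed maximum attainable density (`y_max` trials), so models estimate
#' the probability `m` of attaining the maximum and predicted density is
#' `m * y_max`.
#'
#' @param tiller_density Observed density (tillers ha^-1); vectorised.
#' @param consts A [tiller_constants()] object.
#' @return Tibble with `successes`, `trials`, `proportion`.
#' @export
#' @examples
#' make_response(152842)$proportion  # ~0.51
make_response <- function(tiller_density, consts = tiller_constants()) {
  if (any(tiller_density < 0)) {
    rlang::abort("Negative tiller density", class = "tillerscope_response_error")
  }
  if (any(tiller_density > consts$y_max)) {
    rlang::abort(
      sprintf(paste0("Tiller density %.0f exceeds the assumed maximum ",
                     "attainable density of %.0f tillers/ha"),
              max(tiller_density), consts$y_max),
      class = "tillerscope_response_error"
    )
  }
  successes <- round(tiller_density)
  tibble::tibble(successes = successes, trials = consts$y_max,
                 proportion = successes / consts$y_max)
}

# Columns a spec needs present in the data.
spec_covariates <- function(spec) {
  by_fac <- switch(spec$by,
                   none = character(),
                   pd_class = "pd_class",
                   genotype = "genotype",
                   genotype_pd_class = c("genotype", "pd_class"))
  unique(c(spec$smooths, spec$factors, by_fac))
}

# Prepare model-frame columns: coerce factors, build the genotype-by-class
# crossing, and check that required factor levels are represented.
prepare_model_data <- function(data, spec, training_levels = NULL) {
  df <- tibble::as_tibble(data)
  need <- spec_covariates(spec)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("Data is missing covariate column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tillerscope_schema_error")
  }
  uses_pd_class <- "pd_class" %in% need ||
    spec$by %in% c("pd_class", "genotype_pd_class")
  uses_genotype <- "genotype" %in% need ||
    spec$by %in% c("genotype", "genotype_pd_class")

  if (uses_pd_class) {
    df$pd_class <- if (is.factor(df$pd_class)) {
      factor(as.character(df$pd_class), levels = names(PD_TARGETS))
    } else factor(df$pd_class, levels = names(PD_TARGETS))
    if (anyNA(df$pd_class)) {
      rlang::abort("Unknown plant-density class in data",
                   class = "tillerscope_level_error")
    }
  }
  if (uses_genotype) {
    glev <- if (!is.null(training_levels)) training_levels$genotype
            else sort(unique(as.character(df$genotype)))
    df$genotype <- factor(as.character(df$genotype), levels = glev)
    if (anyNA(df$genotype)) {
      rlang::abort(paste0("Unknown genotype level; trained levels: ",
                          paste(glev, collapse = ", ")),
                   class = "tillerscope_level_error")
    }
  }
  if (spec$by == "genotype_pd_class") {
    df$genotype_pd_class <- interaction(df$genotype, df$pd_class, drop = FALSE)
  }
  # at fit time every level of a fixed-level factor must be observed,
  # otherwise the by-smooth block for that level is unidentifiable
  if (is.null(training_levels)) {
    if (uses_pd_class) {
      absent <- setdiff(names(PD_TARGETS), unique(as.character(df$pd_class)))
      if (length(absent) > 0) {
        rlang::abort(paste0("Plant-density class level(s) absent from ",
                            "training data: ", paste(absent, collapse = ", ")),
                     class = "tillerscope_level_error")
      }
    }
    if (uses_genotype && length(levels(df$genotype)) < 1) {
      rlang::abort("No genotype levels in training data",
                   class = "tillerscope_level_error")
    }
  }
  df
}

# Build the mgcv formula for a spec, adapting each smooth's basis dimension
# to the number of distinct covariate values available.
build_formula <- function(spec, df, consts) {
  by_var <- if (spec$by == "none") NULL else spec$by
  terms <- character()
  fac_terms <- spec$factors
  # drop single-level factor main effects (no contrast to estimate)
  fac_terms <- fac_terms[vapply(fac_terms, function(f) {
    length(unique(as.character(df[[f]]))) > 1
  }, logical(1))]
  if (!is.null(by_var) && !(by_var %in% c(fac_terms, "genotype_pd_class"))) {
    if (by_var %in% FACTOR_COVARIATES &&
        length(unique(as.character(df[[by_var]]))) > 1 &&
        !(by_var %in% fac_terms)) {
      fac_terms <- c(fac_terms, by_var)
    }
  }
  for (v in spec$smooths) {
    k <- min(consts$basis_dim, length(unique(df[[v]])))
    if (k < 3) {
      rlang::abort(
        sprintf("Covariate %s has too few distinct values (%d) to smooth",
                v, length(unique(df[[v]]))),
        class = "tillerscope_fit_error"
      )
    }
    terms <- c(terms,
               if (is.null(by_var)) sprintf("s(%s, k = %d, bs = 'tp')", v, k)
               else sprintf("s(%s, by = %s, k = %d, bs = 'tp')", v, by_var, k))
  }
  rhs <- paste(c(fac_terms, terms), collapse = " + ")
  if (rhs == "") rhs <- "1"
  stats::as.formula(paste(".proportion ~", rhs))
}

# Map coefficient indices to named blocks: one per smooth covariate (all
# by-levels pooled), one per factor main effect, plus the intercept.
coefficient_blocks <- function(gam_fit) {
  blocks <- list()
  n_para <- length(gam_fit$assign)
  para_labels <- attr(gam_fit$pterms, "term.labels")
  blocks[["intercept"]] <- which(gam_fit$assign == 0)
  for (i in seq_along(para_labels)) {
    blocks[[para_labels[i]]] <- which(gam_fit$assign == i)
  }
  for (sm in gam_fit$smooth) {
    v <- sm$term[1]
    idx <- sm$first.para:sm$last.para
    blocks[[v]] <- c(blocks[[v]], idx)
  }
  blocks
}

#' Fit a candidate tiller-density model
#'
#' Fits a penalized binomial generalized additive model on the logit scale:
#' the response is the proportion of the maximum attainable tiller density,
#' weighted by the trial count, with thin-plate regression splines for every
#' continuous covariate (optionally one spline per factor level). Smoothing
#' parameters are selected by REML by default; the quasibinomial family
#' (default) estimates a dispersion parameter, since the large trial count
#' makes nominal binomial variance unrealistically small for field counts.
#' The fit is deterministic.
#'
#' @param data Covariate tibble from [derive_covariates()] (or compatible),
#'   including `tiller_density`.
#' @param spec A [model_spec()]; e.g. one entry of [candidate_registry()].
#' @param consts A [tiller_constants()] object.
#' @return An object of class `tiller_fit` carrying the underlying `gam`
#'   fit, named coefficient blocks per term, the coefficient covariance,
#'   and the training data (for response curves and reference policies).
#' @export
fit_tiller_model <- function(data, spec, consts = tiller_constants()) {
  stopifnot(inherits(spec, "model_spec"))
  df <- prepare_model_data(data, spec)
  resp <- make_response(df$tiller_density, consts)
  df$.proportion <- resp$proportion
  df$.trials <- resp$trials
  fml <- build_formula(spec, df, consts)
  fam <- if (consts$family == "quasibinomial") stats::quasibinomial("logit")
         else stats::binomial("logit")
  # REML-type selection: exact REML via gam() for modest data, the
  # discretized fast-REML equivalent via bam() for larger fits (same
  # criterion, far cheaper with many factor-by smooths; deterministic).
  use_bam <- consts$method == "REML" && nrow(df) >= 500
  fit <- tryCatch(
    if (use_bam) {
      mgcv::bam(fml, family = fam, weights = .trials, data = df,
                method = "fREML", discrete = TRUE)
    } else {
      mgcv::gam(fml, family = fam, weights = .trials, data = df,
                method = consts$method)
    },
    error = function(e) {
      rlang::abort(sprintf("Candidate '%s' failed to fit: %s",
                           spec$name, conditionMessage(e)),
                   class = "tillerscope_fit_error")
    }
  )
  if (!isTRUE(fit$converged %||% TRUE)) {
    rlang::abort(sprintf("Candidate '%s' did not converge (outer iterations: %s)",
                         spec$name, paste(fit$outer.info$iter, collapse = " ")),
                 class = "tillerscope_fit_error")
  }
  levels_used <- list(
    genotype = if ("genotype" %in% names(df) && is.factor(df$genotype))
      levels(df$genotype) else NULL
  )
  structure(
    list(spec = spec, consts = consts, fit = fit,
         beta = stats::coef(fit),
         # smoothing-parameter-uncertainty-corrected covariance when the
         # fitter provides it, else the Bayesian posterior covariance
         Vp = fit$Vc %||% fit$Vp,
         blocks = coefficient_blocks(fit),
         zeroed = character(),
         training_levels = levels_used,
         training_data = dplyr::select(df, -dplyr::any_of(c(".proportion",
                                                            ".trials"))),
         n = nrow(df), deviance = stats::deviance(fit),
         null_deviance = fit$null.deviance,
         scale = fit$sig2 %||% 1, method = consts$method,
         family = consts$family),
    class = "tiller_fit"
  )
}

#' @export
print.tiller_fit <- function(x, ...) {
  cat(sprintf("<tiller_fit> candidate '%s' (%s, %s)\n", x$spec$name,
              x$family, x$method))
  cat(sprintf("  n = %d, deviance = %.1f (null %.1f), scale = %.3g\n",
              x$n, x$deviance, x$null_deviance, x$scale))
  cat(sprintf("  terms: %s\n", paste(setdiff(names(x$blocks), "intercept"),
                                     collapse = ", ")))
  if (length(x$zeroed) > 0) {
    cat(sprintf("  zeroed: %s\n", paste(x$zeroed, collapse = ", ")))
  }
  invisible(x)
}

# Linear-predictor matrix for new data, with factor handling aligned to the
# training levels.
lp_matrix <- function(object, newdata) {
  nd <- prepare_model_data(newdata, object$spec,
                           training_levels = object$training_levels)
  stats::predict(object$fit, newdata = nd, type = "lpmatrix")
}

#' Predict tiller density
#'
#' Maps the linear predictor through the inverse logit to the probability of
#' attaining the maximum tiller density, and scales by `y_max` to the
#' density scale. Predictions honour any terms zeroed with [zero_term()].
#'
#' @param object A `tiller_fit`.
#' @param newdata Covariate tibble; defaults to the training data.
#' @param ... Unused.
#' @return Tibble with `probability` and `tiller_density` columns, one row
#'   per row of `newdata`.
#' @export
predict.tiller_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training_data
  X <- lp_matrix(object, newdata)
  eta <- unname(drop(X %*% object$beta))
  p <- stats::plogis(eta)
  tibble::tibble(probability = p,
                 tiller_density = p * object$consts$y_max)
}

#' Zero a model term's coefficient block
#'
#' Returns a copy of the fitted model in which the entire coefficient block
#' of the named term — all basis coefficients across all factor-by levels of
#' that covariate, or all contrasts of a factor main effect, or the
#' intercept — is set to zero, without refitting. This is the device used in
#' out-of-season error attribution: the term whose removal most reduces a
#' held-out site-year's error is the variable too heavily weighted for that
#' season. Idempotent.
#'
#' @param object A `tiller_fit`.
#' @param term Term name: a smooth covariate (e.g. `"vpd_cum"`), a factor
#'   (e.g. `"pd_class"`), or `"intercept"`.
#' @return A `tiller_fit` with the block zeroed.
#' @export
zero_term <- function(object, term) {
  stopifnot(inherits(object, "tiller_fit"))
  if (!term %in% names(object$blocks)) {
    rlang::abort(paste0("Unknown term '", term, "'; valid terms: ",
                        paste(names(object$blocks), collapse = ", ")),
                 class = "tillerscope_term_error")
  }
  object$beta[object$blocks[[term]]] <- 0
  object$zeroed <- union(object$zeroed, term)
  object
}

#' Zeroable terms of a fitted model
#'
#' @param object A `tiller_fit`.
#' @param include_intercept Include `"intercept"` in the list.
#' @return Character vector of term names accepted by [zero_term()].
#' @export
model_terms <- function(object, include_intercept = FALSE) {
  out <- names(object$blocks)
  if (!include_intercept) out <- setdiff(out, "intercept")
  out
}

#' Simulation-based prediction interval
#'
#' Draws coefficient vectors from the approximate multivariate-normal
#' posterior of the fit (mean = estimated coefficients, covariance = the
#' smoothing-penalty-adjusted Bayesian covariance), maps each draw through
#' the inverse logit and the `y_max` scaling, and returns pointwise
#' quantiles. Coefficient blocks zeroed with [zero_term()] stay zero in
#' every draw. Optionally adds dispersion-scaled response noise on top of
#' coefficient uncertainty.
#'
#' @param object A `tiller_fit`.
#' @param newdata Covariate tibble (one or more rows).
#' @param n_draws Number of posterior draws (>= 200).
#' @param seed Integer seed; draws are reproducible.
#' @param level Interval level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param add_response_noise Add approximate overdispersed-binomial sampling
#'   noise to each draw (default `FALSE`: coefficient uncertainty only).
#' @return Tibble with `tiller_density` (point prediction), `lower`,
#'   `upper`, one row per row of `newdata`; all within \[0, y_max\].
#' @export
prediction_interval <- function(object, newdata, n_draws = 1000, seed = 1,
                                level = 0.95, add_response_noise = FALSE) {
  stopifnot(inherits(object, "tiller_fit"))
  if (n_draws < 200) {
    rlang::abort("n_draws must be at least 200",
                 class = "tillerscope_interval_error")
  }
  if (is.null(object$Vp)) {
    rlang::abort("Fitted model carries no coefficient covariance",
                 class = "tillerscope_interval_error")
  }
  X <- lp_matrix(object, newdata)
  point <- stats::plogis(drop(X %*% object$beta)) * object$consts$y_max
  alpha <- (1 - level) / 2
  withr::with_seed(seed, {
    draws <- MASS::mvrnorm(n_draws, mu = object$beta, Sigma = object$Vp)
    if (n_draws == 1) draws <- matrix(draws, nrow = 1)
    zero_idx <- unlist(object$blocks[object$zeroed], use.names = FALSE)
    if (length(zero_idx) > 0) draws[, zero_idx] <- 0
    p_draws <- stats::plogis(draws %*% t(X))  # n_draws x n_obs
    if (add_response_noise) {
      sd_p <- sqrt(pmax(object$scale, 1) * p_draws * (1 - p_draws) /
                     object$consts$y_max)
      p_draws <- p_draws + stats::rnorm(length(p_draws), 0, sd_p)
      p_draws <- pmin(pmax(p_draws, 0), 1)
    }
    y_draws <- p_draws * object$consts$y_max
    tibble::tibble(
      tiller_density = point,
      lower = apply(y_draws, 2, stats::quantile, probs = alpha),
      upper = apply(y_draws, 2, stats::quantile, probs = 1 - alpha)
    )
  })
}
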