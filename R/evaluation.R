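new_split_plan <- function(mode, train, test, held_out_season = NA,
                           seed = NA) {
  structure(list(mode = mode, train = train, test = test,
                 held_out_season = held_out_season, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d test (%.0f/%.0f)%s\n",
              x$mode, length(x$train), length(x$test),
              100 * length(x$train) / (length(x$train) + length(x$test)),
              100 * length(x$test) / (length(x$train) + length(x$test)),
              if (!is.na(x$held_out_season))
                paste0(", held-out season ", x$held_out_season) else ""))
  invisible(x)
}

#' Cross-season train/test split
#'
#' Randomly splits observations into training and testing sets (default
#' 80/20), stratified by site-year so both sets have similar representation
#' of every site-year. Seeded and reproducible.
#'
#' @param data Observation or covariate tibble with a `site_year` column.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A `split_plan` with `train` and `test` row indices.
#' @export
cross_season_split <- function(data, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) {
    rlang::abort("Training fraction must lie strictly between 0 and 1",
                 class = "tillerscope_split_error")
  }
  idx_by_site <- split(seq_len(nrow(data)), data$site_year)
  withr::with_seed(seed, {
    test <- unlist(lapply(idx_by_site, function(idx) {
      n_test <- round(length(idx) * (1 - fraction))
      if (n_test == 0 || n_test == length(idx)) return(integer())
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  train <- setdiff(seq_len(nrow(data)), test)
  new_split_plan("cross_season", sort(train), sort(test), seed = seed)
}

#' Leave-one-season-out split plans
#'
#' One plan per season: that season's observations form the test set and
#' all other seasons form the training set.
#'
#' @param data Tibble with a `season` column.
#' @return Named list of `split_plan`s, one per season.
#' @export
out_of_season_splits <- function(data) {
  seasons <- sort(unique(data$season))
  if (length(seasons) < 2) {
    rlang::abort("Out-of-season evaluation needs at least two seasons",
                 class = "tillerscope_split_error")
  }
  plans <- lapply(seasons, function(s) {
    test <- which(data$season == s)
    new_split_plan("out_of_season", setdiff(seq_len(nrow(data)), test),
                   test, held_out_season = s)
  })
  stats::setNames(plans, as.character(seasons))
}

#' Mean absolute error and mean bias error
#'
#' MAE is `mean(|predicted - observed|)`; MBE is `mean(predicted -
#' observed)`, so positive bias means over-prediction. Both on the
#' tiller-density scale.
#'
#' @param predicted,observed Equal-length numeric vectors (tillers/ha).
#' @return Tibble with one row: `mae`, `mbe`.
#' @export
#' @examples
#' mae_mbe(c(3, -5), c(0, 0))  # mae 4, mbe -1
mae_mbe <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    rlang::abort("predicted and observed must be non-empty and equal length",
                 class = "tillerscope_metric_error")
  }
  err <- predicted - observed
  tibble::tibble(mae = mean(abs(err)), mbe = mean(err))
}

#' Rank candidate models by held-out error
#'
#' Fits every candidate in the registry on the training rows of a
#' cross-season split, predicts the test rows, and ranks candidates by
#' mean absolute error on the tiller-density scale (ascending; ties keep
#' registry order). Candidates that fail to fit receive infinite MAE with a
#' warning rather than aborting the ranking.
#'
#' @param data Covariate tibble (with `tiller_density`).
#' @param split A `split_plan` from [cross_season_split()].
#' @param registry Named list of [model_spec()]s; default the full
#'   [candidate_registry()].
#' @param consts A [tiller_constants()].
#' @return A tibble of class `tiller_evaluation` with columns `candidate`,
#'   `mae`, `mbe`, `rank`, `selected`; the fitted models are attached as the
#'   `"fits"` attribute.
#' @export
rank_candidates <- function(data, split, registry = candidate_registry(),
                            consts = tiller_constants()) {
  stopifnot(inherits(split, "split_plan"))
  train <- data[split$train, , drop = FALSE]
  test <- data[split$test, , drop = FALSE]
  fits <- vector("list", length(registry))
  names(fits) <- names(registry)
  rows <- purrr::imap(registry, function(spec, nm) {
    fit <- tryCatch(fit_tiller_model(train, spec, consts), error = function(e) {
      warning(sprintf("Candidate '%s' skipped: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    fits[[nm]] <<- fit
    if (is.null(fit)) {
      return(tibble::tibble(candidate = nm, mae = Inf, mbe = NA_real_))
    }
    pred <- predict(fit, test)$tiller_density
    m <- mae_mbe(pred, test$tiller_density)
    tibble::tibble(candidate = nm, mae = m$mae, mbe = m$mbe)
  })
  report <- dplyr::bind_rows(rows)
  if (all(!is.finite(report$mae))) {
    rlang::abort("All candidates failed to fit",
                 class = "tillerscope_fit_error")
  }
  report$rank <- rank(report$mae, ties.method = "first")
  report <- dplyr::arrange(report, .data$rank)
  report$selected <- report$rank == 1
  attr(report, "fits") <- fits
  attr(report, "split") <- split
  class(report) <- c("tiller_evaluation", class(report))
  report
}

#' Out-of-season error attribution by coefficient zeroing
#'
#' For each out-of-season split, fits the given candidate on the training
#' seasons and evaluates each held-out site-year at the reference
#' development stage and plant-density class: the full-model error is the
#' absolute difference between the (averaged) point prediction and the
#' (averaged) observed density for the qualifying plots. Then each model
#' term is independently zeroed ([zero_term()]) and the error recomputed;
#' the term whose exclusion yields the lowest error is reported. Keeping all
#' coefficients is always a candidate exclusion, so the lowest error never
#' exceeds the full error; when no exclusion improves, the excluded-term
#' field is empty.
#'
#' @param data Covariate tibble.
#' @param spec Candidate [model_spec()] (default the `E x M` candidate).
#' @param splits List of out-of-season `split_plan`s; default
#'   [out_of_season_splits()] on `data`.
#' @param reference_class Plant-density class of the point prediction
#'   (default `"B"`, the 42000 plants/ha target).
#' @param stage Development stage of the point prediction (default `"R6"`).
#' @param threshold Acceptable-error threshold (tillers/ha) carried into the
#'   summary (default 10500, 25% of the 42000 plants/ha target).
#' @param consts A [tiller_constants()].
#' @return A tibble of class `tiller_attribution`: `held_out_season`,
#'   `site_year`, `full_error`, `best_excluded_term`, `lowest_error`.
#' @export
attribute_errors <- function(data, spec = candidate_registry()[["E x M"]],
                             splits = NULL, reference_class = "B",
                             stage = "R6", threshold = 10500,
                             consts = tiller_constants()) {
  if (is.null(splits)) splits <- out_of_season_splits(data)
  rows <- purrr::map(splits, function(plan) {
    train <- data[plan$train, , drop = FALSE]
    test <- data[plan$test, , drop = FALSE]
    fit <- fit_tiller_model(train, spec, consts)
    terms <- model_terms(fit)
    purrr::map_dfr(unique(test$site_year), function(sy) {
      q <- test[test$site_year == sy &
                  test$stage == stage &
                  as.character(test$pd_class) == reference_class, ,
                drop = FALSE]
      if (nrow(q) == 0) {
        warning(sprintf(
          "Site-year %s has no stage-%s observation in class %s; skipped",
          sy, stage, reference_class), call. = FALSE)
        return(tibble::tibble())
      }
      observed <- mean(q$tiller_density)
      full_pred <- mean(predict(fit, q)$tiller_density)
      full_error <- abs(full_pred - observed)
      excl <- vapply(terms, function(tm) {
        abs(mean(predict(zero_term(fit, tm), q)$tiller_density) - observed)
      }, numeric(1))
      best <- which.min(excl)
      improved <- excl[best] < full_error
      tibble::tibble(
        held_out_season = plan$held_out_season, site_year = sy,
        full_error = full_error,
        best_excluded_term = if (improved) terms[best] else "",
        lowest_error = unname(if (improved) excl[best] else full_error),
        .term_errors = list(tibble::tibble(term = terms, error = excl))
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "spec") <- spec$name
  class(out) <- c("tiller_attribution", class(out))
  out
}

#' Season-level best exclusion
#'
#' Aggregates an attribution table to one row per held-out season and
#' candidate exclusion: the season MAE of the full model and of each
#' single-term exclusion applied uniformly to all of that season's
#' site-years, with the exclusion minimising the season MAE flagged.
#'
#' @param attribution A `tiller_attribution` from [attribute_errors()].
#' @return Tibble with `held_out_season`, `term` (`"(none)"` for the full
#'   model), `season_mae`, `best`.
#' @export
season_exclusion_mae <- function(attribution) {
  if (!".term_errors" %in% names(attribution)) {
    rlang::abort("Attribution table lacks per-term errors",
                 class = "tillerscope_attribution_error")
  }
  df <- tibble::as_tibble(attribution)
  per_term <- tidyr::unnest(
    dplyr::select(df, "held_out_season", "site_year", ".term_errors"),
    ".term_errors"
  )
  full <- dplyr::summarise(dplyr::group_by(df, .data$held_out_season),
                           season_mae = mean(.data$full_error))
  full$term <- "(none)"
  excl <- dplyr::summarise(
    dplyr::group_by(per_term, .data$held_out_season, .data$term),
    season_mae = mean(.data$error), .groups = "drop"
  )
  out <- dplyr::bind_rows(full[, c("held_out_season", "term", "season_mae")],
                          excl)
  out <- dplyr::group_by(out, .data$held_out_season)
  out <- dplyr::mutate(out, best = .data$season_mae == min(.data$season_mae))
  dplyr::ungroup(out)
}

#' Summarise an attribution table against an error threshold
#'
#' Computes the share of site-years whose lowest attainable error (after
#' the best single-term exclusion) falls below the acceptable-error
#' threshold, and — among the site-years still above it — the share
#' contributed by each held-out season.
#'
#' @param attribution Tibble with `held_out_season` and `lowest_error`
#'   columns, e.g. from [attribute_errors()] or a published attribution
#'   table.
#' @param threshold Acceptable error (tillers/ha); defaults to the table's
#'   `threshold` attribute or 10500.
#' @return List with `pct_below` (percent of site-years below the
#'   threshold), `n_below`, `n_total`, and `failure_share` (tibble of
#'   per-season counts and percentage shares of the remaining failures).
#' @export
summarize_attribution <- function(attribution, threshold = NULL) {
  threshold <- threshold %||% attr(attribution, "threshold") %||% 10500
  below <- attribution$lowest_error < threshold
  failures <- attribution[!below, , drop = FALSE]
  share <- dplyr::count(dplyr::as_tibble(failures), .data$held_out_season,
                        name = "n")
  share$share_pct <- 100 * share$n / max(nrow(failures), 1)
  list(
    pct_below = 100 * mean(below),
    n_below = sum(below),
    n_total = length(below),
    failure_share = share
  )
}

#' Published out-of-season attribution table
#'
#' The out-of-season error-attribution results reported for the 17 Kansas
#' site-years the pipeline emulates: for each held-out season and location,
#' the full-model absolute error of the point prediction (42000 plants/ha
#' target at physiological maturity), the lowest error attainable by
#' independently zeroing one coefficient block, and which coefficient was
#' zeroed (empty when no exclusion improved). Units tillers/ha. Shipped so
#' threshold summaries can be recomputed; see [summarize_attribution()].
#'
#' @return Tibble with columns `held_out_season`, `site`, `full_error`,
#'   `lowest_error`, `zeroed_coefficient`.
#' @export
published_attribution <- function() {
  path <- system.file("extdata", "out_of_season_errors.csv",
                      package = "tillerscope", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    held_out_season = readr::col_integer(),
                    site = readr::col_character(),
                    full_error = readr::col_double(),
                    lowest_error = readr::col_double(),
                    zeroed_coefficient = readr::col_character()
                  ))
}
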