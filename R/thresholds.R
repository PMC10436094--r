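#' Per-covariate response curve of a fitted model
#'
#' Varies one smooth covariate over its training support (optionally within
#' one plant-density class) while holding every other covariate at a
#' reference value — per-class training medians by default, the modal level
#' for factors — and evaluates the modelled probability of attaining the
#' maximum tiller density at each grid point. A centred moving average of
#' the pointwise probabilities is attached; threshold extraction operates on
#' the smoothed curve.
#'
#' @param object A `tiller_fit`.
#' @param covariate Name of a smooth covariate of the model.
#' @param pd_class Density class (`"A"`, `"B"`, `"C"`) to condition on, or
#'   `NULL` for a model without density-class structure.
#' @param n_grid Grid size (default 101).
#' @param ma_window Moving-average window in grid points (odd; default 11).
#' @param reference Reference policy for the held covariates:
#'   `"class_median"` (medians within the conditioning class; default) or
#'   `"global_median"`.
#' @param mode `"grid"` (default) evaluates on an even grid over the
#'   support; `"observed"` evaluates at the sorted observed covariate
#'   values.
#' @return Tibble of class `tiller_curve`: `covariate`, `pd_class`, `x`,
#'   `probability`, `smoothed`.
#' @export
response_curve <- function(object, covariate, pd_class = NULL, n_grid = 101,
                           ma_window = 11,
                           reference = c("class_median", "global_median"),
                           mode = c("grid", "observed")) {
  stopifnot(inherits(object, "tiller_fit"))
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  if (!covariate %in% object$spec$smooths) {
    rlang::abort(paste0("'", covariate, "' is not a smooth term of this ",
                        "model; smooth terms: ",
                        paste(object$spec$smooths, collapse = ", ")),
                 class = "tillerscope_term_error")
  }
  td <- object$training_data
  uses_class <- "pd_class" %in% names(td) &&
    ("pd_class" %in% spec_covariates(object$spec))
  ref_rows <- td
  if (uses_class) {
    if (is.null(pd_class)) pd_class <- "B"
    if (reference == "class_median") {
      ref_rows <- td[as.character(td$pd_class) == pd_class, , drop = FALSE]
      if (nrow(ref_rows) == 0) ref_rows <- td
    }
  }
  support <- if (uses_class)
    td[[covariate]][as.character(td$pd_class) == pd_class]
  else td[[covariate]]
  if (length(support) == 0) support <- td[[covariate]]

  x <- if (mode == "grid") {
    seq(min(support), max(support), length.out = n_grid)
  } else sort(unique(support))

  newdata <- tibble::as_tibble(
    lapply(spec_covariates(object$spec), function(v) {
      if (v == covariate) return(NULL)
      col <- ref_rows[[v]]
      if (is.numeric(col)) stats::median(col)
      else names(sort(table(as.character(col)), decreasing = TRUE))[1]
    }) |> stats::setNames(spec_covariates(object$spec)) |>
      Filter(f = Negate(is.null))
  )
  newdata <- newdata[rep(1, length(x)), , drop = FALSE]
  newdata[[covariate]] <- x
  if (uses_class) newdata$pd_class <- pd_class

  p <- predict(object, newdata)$probability
  if (ma_window %% 2 == 0) ma_window <- ma_window + 1
  # centred moving average, symmetrically shrunk near the edges (an
  # asymmetric partial window would bias the smoothed curve toward interior
  # values exactly where low-support thresholds live)
  h <- (ma_window - 1) / 2
  n_pts <- length(p)
  smoothed <- vapply(seq_len(n_pts), function(i) {
    hi <- min(h, i - 1, n_pts - i)
    mean(p[(i - hi):(i + hi)])
  }, numeric(1))
  out <- tibble::tibble(covariate = covariate,
                        pd_class = if (uses_class) pd_class else NA_character_,
                        x = x, probability = p, smoothed = smoothed)
  class(out) <- c("tiller_curve", class(out))
  out
}

#' Extract 0.50-probability limiting thresholds from a response curve
#'
#' Finds every point where the (smoothed) response curve crosses the
#' threshold probability, by linear interpolation between the adjacent grid
#' points bracketing it. Each crossing carries a direction: `"rising"`
#' (probability increases through the threshold, so the covariate is
#' non-limiting above the crossing) or `"falling"` (limiting above). A
#' curve that never crosses returns zero rows.
#'
#' @param curve A `tiller_curve`, or any tibble with an `x` column and a
#'   `smoothed` (or `probability`) column.
#' @param prob Threshold probability (default 0.50).
#' @return Tibble of class `tiller_thresholds`: `covariate`, `pd_class`,
#'   `crossing` (covariate units, ascending), `direction`.
#' @export
#' @examples
#' extract_thresholds(tibble::tibble(x = c(100, 300),
#'                                   probability = c(0.2, 0.6)))
extract_thresholds <- function(curve, prob = 0.5) {
  p_all <- curve[["smoothed"]] %||% curve[["probability"]]
  keep <- !is.na(p_all)
  x <- curve$x[keep]
  p <- p_all[keep]
  if (length(x) < 2) {
    rlang::abort("Curve needs at least two non-missing grid points",
                 class = "tillerscope_curve_error")
  }
  crossings <- numeric()
  directions <- character()
  d <- p - prob
  for (i in seq_len(length(x) - 1)) {
    if (d[i] == 0) {
      # exact hit at a grid point: a crossing only if the sign changes around it
      lo <- if (i > 1) d[i - 1] else 0
      if (lo * d[i + 1] < 0 || (i == 1 && d[i + 1] != 0)) {
        crossings <- c(crossings, x[i])
        directions <- c(directions,
                        if (d[i + 1] > 0) "rising" else "falling")
      }
    } else if (d[i] * d[i + 1] < 0) {
      xstar <- x[i] + (prob - p[i]) * (x[i + 1] - x[i]) / (p[i + 1] - p[i])
      crossings <- c(crossings, xstar)
      directions <- c(directions, if (p[i + 1] > p[i]) "rising" else "falling")
    }
  }
  out <- tibble::tibble(
    covariate = if ("covariate" %in% names(curve))
      rep(curve$covariate[1], length(crossings)) else
        rep(NA_character_, length(crossings)),
    pd_class = if ("pd_class" %in% names(curve))
      rep(curve$pd_class[1], length(crossings)) else
        rep(NA_character_, length(crossings)),
    crossing = crossings,
    direction = directions
  )
  attr(out, "prob") <- prob
  class(out) <- c("tiller_thresholds", class(out))
  out
}
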