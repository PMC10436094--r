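#' Tidy a fitted tiller-density model
#'
#' Returns one row per model term in broom convention. Smooth terms carry
#' effective degrees of freedom and the approximate significance test from
#' the underlying fit; parametric terms carry coefficient estimates.
#'
#' @param x A `tiller_fit`.
#' @param type `"smooth"` (default) or `"parametric"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tiller_fit <- function(x, type = c("smooth", "parametric"), ...) {
  type <- match.arg(type)
  s <- summary(x$fit)
  if (type == "smooth") {
    st <- s$s.table
    if (is.null(st) || nrow(st) == 0) return(tibble::tibble(
      term = character(), edf = numeric(), ref_df = numeric(),
      statistic = numeric(), p_value = numeric()))
    tibble::tibble(
      term = rownames(st), edf = st[, "edf"], ref_df = st[, "Ref.df"],
      statistic = st[, 3], p_value = st[, 4]
    )
  } else {
    pt <- s$p.table
    tibble::tibble(
      term = rownames(pt), estimate = pt[, 1], std_error = pt[, 2],
      statistic = pt[, 3], p_value = pt[, 4]
    )
  }
}

#' One-row model summary
#'
#' @param x A `tiller_fit`.
#' @param ... Unused.
#' @return Tibble with candidate name, sample size, deviance, deviance
#'   explained, dispersion, family and smoothing method.
#' @export
glance.tiller_fit <- function(x, ...) {
  tibble::tibble(
    candidate = x$spec$name,
    n = x$n,
    deviance = x$deviance,
    null_deviance = x$null_deviance,
    deviance_explained = 1 - x$deviance / x$null_deviance,
    dispersion = x$scale,
    family = x$family,
    method = x$method
  )
}

#' Training data with fitted values attached
#'
#' @param x A `tiller_fit`.
#' @param ... Unused.
#' @return The training tibble plus `.fitted_probability` and
#'   `.fitted_density`.
#' @export
augment.tiller_fit <- function(x, ...) {
  pred <- predict(x)
  dplyr::mutate(x$training_data,
                .fitted_probability = pred$probability,
                .fitted_density = pred$tiller_density)
}
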