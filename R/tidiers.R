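#' Tidy a driver model
#'
#' One row per selected predictor: standardized coefficient, standard error,
#' p-value, significance stars, independent contribution and relative
#' importance from hierarchical partitioning, and the diversity dimension.
#'
#' @param x A `driver_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy driver_fit
#' @export
tidy.driver_fit <- function(x, ...) {
  x$coefficients |>
    dplyr::left_join(dplyr::select(x$hp, "term", "independent", "rel_importance"),
                     by = "term") |>
    dplyr::left_join(dimension_map(), by = "term") |>
    dplyr::mutate(stratum = x$stratum, interval = x$interval, .before = 1)
}

#' One-row summary of a driver model
#'
#' @param x A `driver_fit`.
#' @param ... Unused.
#' @return A tibble with stratum, interval, n, numbers of candidate /
#'   VIF-dropped / selected predictors, AIC, R2, and the top dimension.
#' @method glance driver_fit
#' @export
glance.driver_fit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, interval = x$interval, n = x$n,
    n_candidates = length(x$candidates),
    n_vif_dropped = nrow(x$vif_dropped),
    n_selected = length(x$selected),
    aic = x$aic, r2 = x$r2,
    top_dimension = x$dimensions$dimension[1],
    top_dimension_importance = x$dimensions$rel_importance[1]
  )
}

#' Tidy all cells of a driver analysis
#' @param x A `driver_analysis`.
#' @param ... Unused.
#' @return Stacked [tidy.driver_fit()] rows.
#' @method tidy driver_analysis
#' @export
tidy.driver_analysis <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @rdname glance.driver_fit
#' @method glance driver_analysis
#' @export
glance.driver_analysis <- function(x, ...) x$summary
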