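#' Forest-style coefficient plot of a driver model
#'
#' Standardized effects with 95% confidence bars; filled points are
#' significant at 0.05, open points are retained-but-nonsignificant, mirroring
#' the convention of biodiversity-effect figures.
#'
#' @param object A `driver_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot driver_fit
#' @export
autoplot.driver_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(sig = .data$p.value < 0.05,
                  term = stats::reorder(.data$term, .data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$sig, colour = .data$dimension),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(
      title = sprintf("Drivers of biomass change: %s, interval %s",
                      object$stratum, object$interval),
      x = "standardized effect on ΔAGB", y = NULL, colour = "dimension") +
    ggplot2::theme_minimal()
}

#' Grouped relative-importance plot across model cells
#'
#' Stacked bars of per-dimension relative importance (%) for every
#' interval x stratum driver model.
#'
#' @param analysis A `driver_analysis`.
#' @return A ggplot.
#' @export
plot_dimension_importance <- function(analysis) {
  stopifnot(inherits(analysis, "driver_analysis"))
  df <- purrr::imap_dfr(analysis$fits, function(f, nm) {
    dplyr::mutate(f$dimensions, stratum = f$stratum,
                  interval = paste("interval", f$interval))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$rel_importance,
                                   fill = .data$dimension)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~interval) +
    ggplot2::labs(x = NULL, y = "relative importance (%)", fill = "dimension") +
    ggplot2::theme_minimal()
}

#' Biomass trajectories across censuses
#'
#' Mean quadrat AGB (with standard deviation ribbons) per census, overall and
#' by habitat stratum.
#'
#' @param agb [quadrat_agb()] output.
#' @param habitat_map Optional `quadrat`/`habitat` table for faceting.
#' @return A ggplot.
#' @export
plot_agb_trajectory <- function(agb, habitat_map = NULL) {
  if (!is.null(habitat_map)) {
    agb <- dplyr::left_join(agb, dplyr::select(habitat_map, "quadrat", "habitat"),
                            by = "quadrat")
  } else {
    agb$habitat <- "whole plot"
  }
  df <- agb |>
    dplyr::group_by(.data$habitat, .data$census) |>
    dplyr::summarise(mean = mean(.data$agb), sd = sd(.data$agb), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$census, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey85") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~habitat) +
    ggplot2::labs(x = "census", y = "AGB (Mg/ha)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
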