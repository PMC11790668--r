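#' Quadrat topographic variables from a corner-elevation grid
#'
#' Computes the four standard forest-dynamics-plot topographic variables for
#' every quadrat of a rectangular grid, from the elevations surveyed at
#' quadrat corners:
#'
#' * **elevation** -- mean of the quadrat's four corner elevations (m);
#' * **slope** -- mean angular slope (degrees) of the four planes obtained by
#'   omitting each corner in turn;
#' * **aspect** -- compass bearing (degrees clockwise from north, `[0, 360)`)
#'   of the downslope direction of the least-squares plane through the four
#'   corners; undefined (`NA`) on perfectly flat quadrats;
#' * **convexity** -- quadrat elevation minus the mean elevation of its
#'   eight neighbouring quadrats (m); quadrats on the plot edge instead use
#'   the elevation of the quadrat centre minus the mean of the quadrat's own
#'   corners, which is exactly zero when the centre is interpolated
#'   bilinearly from the surveyed corners, as here.
#'
#' @param elevation Numeric matrix of corner elevations, dimension
#'   `(rows+1) x (cols+1)`. Row index increases northward, column index
#'   eastward; `elevation[i, j]` is the corner at the i-th south-to-north and
#'   j-th west-to-east grid line.
#' @param quadrat_side Quadrat side length in m (default 20).
#' @return A tibble with `quadrat`, `col`, `row`, `elevation`, `slope`,
#'   `aspect`, `convexity`.
#' @export
quadrat_topography <- function(elevation, quadrat_side = 20) {
  elevation <- as.matrix(elevation)
  if (nrow(elevation) < 2 || ncol(elevation) < 2 || !is.numeric(elevation)) {
    stop("`elevation` must be a numeric corner grid of at least 2 x 2", call. = FALSE)
  }
  if (anyNA(elevation)) stop("`elevation` contains missing corners", call. = FALSE)
  s <- quadrat_side
  nrq <- nrow(elevation) - 1
  ncq <- ncol(elevation) - 1

  elev <- matrix(NA_real_, nrq, ncq)
  slope <- matrix(NA_real_, nrq, ncq)
  aspect <- matrix(NA_real_, nrq, ncq)
  for (r in seq_len(nrq)) {
    for (c in seq_len(ncq)) {
      # corners: z00 SW, z10 SE, z01 NW, z11 NE
      z00 <- elevation[r, c]; z10 <- elevation[r, c + 1]
      z01 <- elevation[r + 1, c]; z11 <- elevation[r + 1, c + 1]
      elev[r, c] <- mean(c(z00, z10, z01, z11))
      # four 3-corner planes, omitting each corner in turn
      grads <- rbind(
        c((z10 - z00) / s, (z01 - z00) / s),  # omit NE
        c((z11 - z01) / s, (z01 - z00) / s),  # omit SE
        c((z10 - z00) / s, (z11 - z10) / s),  # omit NW
        c((z11 - z01) / s, (z11 - z10) / s)   # omit SW
      )
      slope[r, c] <- mean(atan(sqrt(rowSums(grads^2)))) * 180 / pi
      # least-squares plane through the 4 corners
      gx <- ((z10 + z11) - (z00 + z01)) / (2 * s)
      gy <- ((z01 + z11) - (z00 + z10)) / (2 * s)
      if (gx == 0 && gy == 0) {
        aspect[r, c] <- NA_real_
      } else {
        aspect[r, c] <- (atan2(-gx, -gy) * 180 / pi) %% 360
      }
    }
  }
  convex <- matrix(0, nrq, ncq)  # edge quadrats: bilinear centre - corner mean = 0
  if (nrq > 2 && ncq > 2) {
    for (r in 2:(nrq - 1)) {
      for (c in 2:(ncq - 1)) {
        nb <- elev[(r - 1):(r + 1), (c - 1):(c + 1)]
        convex[r, c] <- elev[r, c] - (sum(nb) - elev[r, c]) / 8
      }
    }
  }
  tidyr::expand_grid(row = seq_len(nrq), col = seq_len(ncq)) |>
    dplyr::mutate(
      quadrat = quadrat_id(.data$col, .data$row),
      elevation = purrr::map2_dbl(.data$row, .data$col, ~elev[.x, .y]),
      slope = purrr::map2_dbl(.data$row, .data$col, ~slope[.x, .y]),
      aspect = purrr::map2_dbl(.data$row, .data$col, ~aspect[.x, .y]),
      convexity = purrr::map2_dbl(.data$row, .data$col, ~convex[.x, .y])
    ) |>
    dplyr::select("quadrat", "col", "row", "elevation", "slope", "aspect", "convexity") |>
    dplyr::arrange(.data$col, .data$row)
}

#' Canonical quadrat identifier from grid coordinates
#' @param col,row 1-based grid column (west to east) and row (south to north).
#' @return Character vector like `"c03r07"`.
#' @export
quadrat_id <- function(col, row) sprintf("c%02dr%02d", col, row)

#' Attach habitat labels to quadrats
#'
#' Joins an externally supplied habitat classification (`H1` low-valley,
#' `H2` mid-hillside, `H3` high-ridge) onto a quadrat table and reports the
#' per-habitat quadrat counts.
#'
#' @param frame Quadrat table with a `quadrat` column (e.g. from
#'   [quadrat_topography()]).
#' @param habitat_map Data frame with columns `quadrat`, `habitat`.
#' @param quiet Suppress the count message.
#' @return `frame` with a `habitat` factor column.
#' @export
assign_habitats <- function(frame, habitat_map, quiet = FALSE) {
  stopifnot(is.data.frame(frame), is.data.frame(habitat_map))
  bad <- setdiff(unique(habitat_map$habitat), c("H1", "H2", "H3"))
  if (length(bad) > 0) {
    offenders <- habitat_map$quadrat[habitat_map$habitat %in% bad]
    stop("unknown habitat label(s) ", paste(bad, collapse = ", "),
         " for quadrat(s): ", paste(head(offenders, 10), collapse = ", "),
         call. = FALSE)
  }
  missing_q <- setdiff(frame$quadrat, habitat_map$quadrat)
  if (length(missing_q) > 0) {
    stop("quadrats without habitat label: ",
         paste(head(missing_q, 10), collapse = ", "), call. = FALSE)
  }
  out <- frame |>
    dplyr::left_join(dplyr::select(habitat_map, "quadrat", "habitat"), by = "quadrat") |>
    dplyr::mutate(habitat = factor(.data$habitat, levels = c("H1", "H2", "H3")))
  if (!quiet) {
    counts <- table(out$habitat)
    message("habitat counts: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  out
}
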