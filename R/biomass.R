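#' Tree height from diameter allometry
#'
#' Height is predicted from diameter at breast height by the power law
#' `H = a * D^b * CF`, where `CF` is the correction factor that undoes the
#' back-transformation bias of a log-log regression fit. Coefficients are
#' species specific where available; a pooled all-species set is used for the
#' remainder (see [quadrat_agb()]).
#'
#' @param dbh Diameter at breast height in cm. Vectorised.
#' @param a,b Allometric coefficient and exponent; both must be positive.
#' @param cf Correction factor (> 0). Defaults to 1 (no correction).
#' @return Predicted height in m, same length as `dbh`.
#' @examples
#' estimate_height(10, a = 2, b = 0.5, cf = 1.05)
#' @export
estimate_height <- function(dbh, a, b, cf = 1) {
  if (any(!is.finite(dbh) | dbh <= 0)) {
    stop("`dbh` must be positive and finite", call. = FALSE)
  }
  if (any(a <= 0) || any(b <= 0) || any(cf <= 0)) {
    stop("allometric coefficients `a`, `b`, `cf` must be positive", call. = FALSE)
  }
  a * dbh^b * cf
}

#' Stem aboveground biomass from diameter, wood density and height
#'
#' The pantropical-style compound allometry
#' `AGB = 0.0673 * (WD * D^2 * H)^0.976` with `D` in cm, `WD` in g/cm3 and
#' `H` in m, returning kg per stem. The constant and exponent are exposed so
#' alternative calibrations can be swapped in.
#'
#' @param dbh Diameter at breast height, cm.
#' @param wd Wood density, g/cm3.
#' @param height Tree height, m.
#' @param coef,exponent Allometry constant and exponent.
#' @return Stem aboveground biomass in kg.
#' @examples
#' estimate_stem_agb(dbh = 10, wd = 0.5, height = 10)
#' @export
estimate_stem_agb <- function(dbh, wd, height, coef = 0.0673, exponent = 0.976) {
  if (any(!is.finite(dbh) | dbh <= 0) || any(!is.finite(wd) | wd <= 0) ||
      any(!is.finite(height) | height <= 0)) {
    stop("`dbh`, `wd` and `height` must all be positive and finite", call. = FALSE)
  }
  coef * (wd * dbh^2 * height)^exponent
}

#' Fill missing wood density from taxonomic relatives
#'
#' Missing wood densities are imputed, in order of preference, by the mean of
#' congeners with observed values in the same climate region, then
#' confamilials, then the pool-wide mean (with a warning, since that fallback
#' carries no taxonomic signal). The provenance of every value is recorded in
#' a `wd_source` column (`"observed"`, `"genus"`, `"family"`, `"pool"`).
#'
#' @param species A species table with at least `species`, `genus`, `family`
#'   and `wd` columns; an optional `region` column scopes the genus/family
#'   means (absent = one region).
#' @return The species table with `wd` complete and a `wd_source` column.
#' @export
impute_wood_density <- function(species) {
  stopifnot(is.data.frame(species))
  if (nrow(species) == 0) stop("empty species table", call. = FALSE)
  req <- c("species", "genus", "family", "wd")
  if (!all(req %in% names(species))) {
    stop("species table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (all(is.na(species$wd))) {
    stop("no observed wood density anywhere in the pool", call. = FALSE)
  }
  if (any(species$wd[!is.na(species$wd)] <= 0)) {
    stop("observed wood densities must be positive", call. = FALSE)
  }
  out <- dplyr::as_tibble(species)
  if (!"region" %in% names(out)) out$region <- "all"

  obs <- dplyr::filter(out, !is.na(.data$wd))
  genus_means <- obs |>
    dplyr::group_by(.data$region, .data$genus) |>
    dplyr::summarise(wd_genus = mean(.data$wd), .groups = "drop")
  family_means <- obs |>
    dplyr::group_by(.data$region, .data$family) |>
    dplyr::summarise(wd_family = mean(.data$wd), .groups = "drop")
  pool_mean <- mean(obs$wd)

  out <- out |>
    dplyr::left_join(genus_means, by = c("region", "genus")) |>
    dplyr::left_join(family_means, by = c("region", "family")) |>
    dplyr::mutate(
      wd_source = dplyr::case_when(
        !is.na(.data$wd) ~ "observed",
        !is.na(.data$wd_genus) ~ "genus",
        !is.na(.data$wd_family) ~ "family",
        TRUE ~ "pool"
      ),
      wd = dplyr::coalesce(.data$wd, .data$wd_genus, .data$wd_family, pool_mean)
    ) |>
    dplyr::select(-"wd_genus", -"wd_family")
  n_pool <- sum(out$wd_source == "pool")
  if (n_pool > 0) {
    warning(n_pool, " species imputed from the pool-wide mean (no genus or family data)",
            call. = FALSE)
  }
  out
}

#' Quadrat-level aboveground biomass density
#'
#' Sums stem biomass (kg) over all alive tagged stems in each quadrat --
#' including every stem of multi-stemmed trees -- and converts to Mg per
#' hectare (`/1000` kg to Mg, `* 10000/area` m2 to ha). Species without
#' fitted height coefficients fall back to the pooled all-species set, with a
#' message reporting how many stems that covered. Dead stems contribute zero.
#'
#' @param census Stem table with columns `tree_id`, `stem_id`, `species`,
#'   `quadrat`, `dbh`, `census`, `status`.
#' @param species Species table with complete `wd` (see
#'   [impute_wood_density()]) and height coefficients `a`, `b`, `cf`
#'   (`NA` where unfitted).
#' @param quadrat_area Quadrat area in m2 (default 400, a 20 m quadrat).
#' @param pooled Named vector `c(a=, b=, cf=)` of pooled all-species height
#'   coefficients; defaults to the `pooled_height` attribute of `species`.
#' @param quadrats Optional vector of quadrat ids to report (zero-stem
#'   quadrats then appear with 0 biomass); defaults to those in `census`.
#' @param quiet Suppress the pooled-coefficient message.
#' @return A tibble with `quadrat`, `census`, `agb` (Mg/ha).
#' @export
quadrat_agb <- function(census, species, quadrat_area = 400,
                        pooled = attr(species, "pooled_height"),
                        quadrats = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(census), is.data.frame(species), quadrat_area > 0)
  if (is.null(pooled)) pooled <- c(a = 1.5, b = 0.6, cf = 1.02)
  unknown <- setdiff(unique(census$species[census$status == "alive"]), species$species)
  if (length(unknown) > 0) {
    stop("census species absent from species table: ",
         paste(head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(species$wd))) {
    stop("species table has missing wood density; run impute_wood_density() first",
         call. = FALSE)
  }
  alive <- dplyr::filter(census, .data$status == "alive")
  sp <- dplyr::select(species, "species", "wd", "a", "b", "cf")
  alive <- dplyr::left_join(alive, sp, by = "species")
  pooled_used <- is.na(alive$a) | is.na(alive$b)
  alive$a[pooled_used] <- pooled[["a"]]
  alive$b[pooled_used] <- pooled[["b"]]
  alive$cf[pooled_used] <- pooled[["cf"]]
  alive$cf[is.na(alive$cf)] <- 1
  if (!quiet && any(pooled_used)) {
    message(sum(pooled_used), " stems used pooled all-species height coefficients")
  }
  if (nrow(alive) > 0) {
    h <- estimate_height(alive$dbh, alive$a, alive$b, alive$cf)
    alive$agb_kg <- estimate_stem_agb(alive$dbh, alive$wd, h)
  } else {
    alive$agb_kg <- numeric(0)
  }
  if (is.null(quadrats)) quadrats <- sort(unique(census$quadrat))
  per_census <- sort(unique(census$census))
  grid <- tidyr::expand_grid(quadrat = quadrats, census = per_census)
  alive |>
    dplyr::group_by(.data$quadrat, .data$census) |>
    dplyr::summarise(agb = sum(.data$agb_kg) / 1000 * 10000 / quadrat_area,
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("quadrat", "census")) |>
    dplyr::mutate(agb = dplyr::coalesce(.data$agb, 0)) |>
    dplyr::arrange(.data$census, .data$quadrat)
}

#' Per-quadrat change in aboveground biomass between censuses
#'
#' @param agb Output of [quadrat_agb()] covering all requested censuses.
#' @param pairs List of length-2 vectors `(from, to)`; defaults to
#'   consecutive censuses in sorted order.
#' @return A tibble `quadrat`, `interval` (1-based index of the pair),
#'   `census_from`, `census_to`, `d_agb` (Mg/ha, later minus earlier).
#' @export
delta_agb <- function(agb, pairs = NULL) {
  stopifnot(is.data.frame(agb), all(c("quadrat", "census", "agb") %in% names(agb)))
  censuses <- sort(unique(agb$census))
  if (is.null(pairs)) {
    if (length(censuses) < 2) stop("need at least two censuses", call. = FALSE)
    pairs <- Map(c, censuses[-length(censuses)], censuses[-1])
  }
  purrr::imap_dfr(pairs, function(pr, i) {
    a1 <- dplyr::filter(agb, .data$census == pr[[1]])
    a2 <- dplyr::filter(agb, .data$census == pr[[2]])
    miss <- c(setdiff(a1$quadrat, a2$quadrat), setdiff(a2$quadrat, a1$quadrat))
    if (length(miss) > 0) {
      stop("quadrats missing in one census of pair (", pr[[1]], ",", pr[[2]], "): ",
           paste(head(miss, 10), collapse = ", "), call. = FALSE)
    }
    dplyr::inner_join(a1, a2, by = "quadrat", suffix = c("_from", "_to")) |>
      dplyr::transmute(
        quadrat = .data$quadrat,
        interval = i,
        census_from = pr[[1]], census_to = pr[[2]],
        d_agb = .data$agb_to - .data$agb_from
      )
  })
}
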