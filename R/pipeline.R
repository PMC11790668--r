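#' Per-quadrat, per-census diversity profile across four dimensions
#'
#' Computes the eleven quadrat-level biotic covariates for every census:
#' taxonomic (`H`, `D`, `J`), structural (`SD`, `CV_DBH`), phylogenetic
#' (`MPD`, `MNTD` as null-standardized effect sizes on phylogenetic
#' cophenetic distances) and functional (`traitMPD`, `traitMNTD` as
#' sign-flipped SES on trait-dendrogram distances; `FDis`, `RaoQ` on the raw
#' Gower matrix).
#'
#' @param censuses Stem table covering all censuses.
#' @param species Species table with complete wood density and traits (run
#'   [impute_wood_density()] first).
#' @param phylogeny An `ape::phylo` over (at least) the census species.
#' @param null A [null_spec()] for the SES metrics.
#' @param quadrats Optional quadrat ids (defaults to those in `censuses`).
#' @param min_dbh Inclusion threshold, cm.
#' @param simpson,weighted Passed to [taxonomic_indices()] / [ses_metric()].
#' @param indices Which indices to compute (default all eleven); computing a
#'   subset skips the unneeded distance matrices and null models.
#' @return Tibble: `quadrat`, `census`, `richness`, and the requested indices.
#' @export
diversity_profile <- function(censuses, species, phylogeny, null = null_spec(),
                              quadrats = NULL, min_dbh = 1,
                              simpson = "gini", weighted = FALSE,
                              indices = c("H", "D", "J", "SD", "CV_DBH",
                                          "MPD", "MNTD", "traitMPD", "traitMNTD",
                                          "FDis", "RaoQ")) {
  stopifnot(is.data.frame(censuses), inherits(phylogeny, "phylo"))
  indices <- match.arg(indices, several.ok = TRUE)
  if (is.null(quadrats)) quadrats <- sort(unique(censuses$quadrat))
  census_species <- sort(unique(censuses$species))
  missing_tips <- setdiff(census_species, phylogeny$tip.label)
  if (length(missing_tips) > 0) {
    stop("census species absent from phylogeny: ",
         paste(head(missing_tips, 10), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(phylogeny$tip.label, census_species)
  if (length(extra) > 0) {
    phylogeny <- ape::drop.tip(phylogeny, extra)
    message("pruned ", length(extra), " phylogeny tip(s) absent from censuses")
  }
  need_phy <- any(c("MPD", "MNTD") %in% indices)
  need_trait <- any(c("traitMPD", "traitMNTD", "FDis", "RaoQ") %in% indices)
  phy_d <- if (need_phy) ape::cophenetic.phylo(phylogeny) else NULL
  td <- if (need_trait) {
    trait_distances(dplyr::filter(species, .data$species %in% census_species))
  } else NULL

  purrr::map_dfr(sort(unique(censuses$census)), function(cs) {
    comm <- community_matrix(censuses, cs, min_dbh = min_dbh, quadrats = quadrats)
    out <- tibble::tibble(quadrat = rownames(comm), census = cs,
                          richness = as.integer(rowSums(comm > 0)))
    if (any(c("H", "D", "J") %in% indices)) {
      tax <- taxonomic_indices(comm, simpson = simpson)
      out$H <- tax$H; out$D <- tax$D; out$J <- tax$J
    }
    if (any(c("SD", "CV_DBH") %in% indices)) {
      struct <- structural_indices(dplyr::filter(censuses, .data$census == cs),
                                   min_dbh = min_dbh, quadrats = quadrats)
      i <- match(rownames(comm), struct$quadrat)
      out$SD <- struct$SD[i]; out$CV_DBH <- struct$CV_DBH[i]
    }
    if ("MPD" %in% indices) {
      out$MPD <- ses_metric(comm, phy_d, "MPD", null = null, weighted = weighted)$ses
    }
    if ("MNTD" %in% indices) {
      out$MNTD <- ses_metric(comm, phy_d, "MNTD", null = null, weighted = weighted)$ses
    }
    if ("traitMPD" %in% indices) {
      out$traitMPD <- ses_metric(comm, td$dendrogram, "MPD", null = null,
                                 sign_flip = TRUE, weighted = weighted)$ses
    }
    if ("traitMNTD" %in% indices) {
      out$traitMNTD <- ses_metric(comm, td$dendrogram, "MNTD", null = null,
                                  sign_flip = TRUE, weighted = weighted)$ses
    }
    if (any(c("FDis", "RaoQ") %in% indices)) {
      fd <- functional_dispersion(comm, td$gower)
      if ("FDis" %in% indices) out$FDis <- fd$FDis
      if ("RaoQ" %in% indices) out$RaoQ <- fd$RaoQ
    }
    dplyr::select(out, "quadrat", "census", "richness",
                  dplyr::all_of(intersect(c("H", "D", "J", "SD", "CV_DBH", "MPD",
                                            "MNTD", "traitMPD", "traitMNTD",
                                            "FDis", "RaoQ"), indices)))
  })
}

#' Assemble the per-quadrat covariate table for the driver analysis
#'
#' Joins, for every interval, the biomass change (response), the topographic
#' variables, the initial-census diversity indices and their interval change
#' values, plus the habitat label. This is the table [run_driver_analysis()]
#' consumes.
#'
#' @param delta [delta_agb()] output.
#' @param profile [diversity_profile()] output.
#' @param changes [change_values()] output on the same profile.
#' @param topography [quadrat_topography()] output with habitats attached.
#' @return Tibble keyed by `quadrat` x `interval`.
#' @export
diversity_covariates <- function(delta, profile, changes, topography) {
  topo_cols <- c("quadrat", "habitat", "elevation", "slope", "aspect", "convexity")
  stopifnot(all(topo_cols %in% c(names(topography), "habitat")))
  idx_cols <- setdiff(names(profile), c("quadrat", "census", "richness"))
  out <- delta |>
    dplyr::left_join(dplyr::select(topography, dplyr::any_of(topo_cols)), by = "quadrat") |>
    dplyr::left_join(dplyr::select(profile, "quadrat", "census",
                                   dplyr::all_of(idx_cols)),
                     by = c("quadrat", "census_from" = "census")) |>
    dplyr::left_join(dplyr::select(changes, -"census_from", -"census_to"),
                     by = c("quadrat", "interval"))
  dplyr::relocate(out, "quadrat", "interval", "habitat", "d_agb")
}

#' Run the whole analysis pipeline on a study
#'
#' Chains biomass estimation, topography, the diversity profile and its
#' change values, the census-to-census rank-sum comparisons, and the per
#' interval x stratum driver models. With the default three censuses and
#' three habitats this yields 8 driver-model cells (2 intervals x
#' \{whole, H1, H2, H3\}).
#'
#' @param study An `agb_study` (from [simulate_study()] or [read_study()]).
#' @param null A [null_spec()]; its seed defaults to the study seed.
#' @param quadrat_area Quadrat area, m2.
#' @param strata,intervals,vif_threshold,max_exhaustive,min_n Passed to
#'   [run_driver_analysis()].
#' @param quiet Suppress progress messages.
#' @return List of class `agb_pipeline`: `agb`, `delta`, `topography`,
#'   `wilcoxon`, `profile`, `changes`, `covariates`, `drivers`.
#' @export
run_pipeline <- function(study, null = NULL, quadrat_area = NULL,
                         strata = NULL, intervals = NULL, vif_threshold = 5,
                         max_exhaustive = 15, min_n = 10, quiet = TRUE) {
  stopifnot(inherits(study, "agb_study"))
  cfg <- study$config
  if (is.null(null)) null <- cfg$null %||% null_spec(seed = cfg$seed)
  if (is.null(quadrat_area)) quadrat_area <- cfg$quadrat_side^2
  maybe_quiet <- if (quiet) suppressMessages else identity

  maybe_quiet({
    species <- impute_wood_density(study$species)
    quadrats <- study$landscape$quadrats$quadrat
    agb <- quadrat_agb(study$censuses, species, quadrat_area = quadrat_area,
                       pooled = study$pooled_height, quadrats = quadrats, quiet = TRUE)
    delta <- delta_agb(agb)
    topo <- quadrat_topography(study$landscape$elevation,
                               quadrat_side = cfg$quadrat_side) |>
      assign_habitats(study$landscape$quadrats, quiet = TRUE)
    wil <- wilcoxon_compare(agb, habitat_map = study$landscape$quadrats)
    profile <- diversity_profile(study$censuses, species, study$phylogeny,
                                 null = null, quadrats = quadrats)
    changes <- change_values(profile)
    covs <- diversity_covariates(delta, profile, changes, topo)
    drivers <- run_driver_analysis(covs, strata = strata, intervals = intervals,
                                   vif_threshold = vif_threshold,
                                   max_exhaustive = max_exhaustive, min_n = min_n)
  })
  structure(list(agb = agb, delta = delta, topography = topo, wilcoxon = wil,
                 profile = profile, changes = changes, covariates = covs,
                 drivers = drivers, config = cfg),
            class = "agb_pipeline")
}

#' @export
print.agb_pipeline <- function(x, ...) {
  cat("agb_pipeline:", length(unique(x$agb$census)), "censuses,",
      length(unique(x$agb$quadrat)), "quadrats,",
      length(x$drivers$fits), "driver-model cells\n")
  agb_means <- x$agb |>
    dplyr::group_by(.data$census) |>
    dplyr::summarise(mean_agb = mean(.data$agb), sd_agb = sd(.data$agb))
  print(agb_means, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
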