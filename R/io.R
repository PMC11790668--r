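#' Write a study to a directory of plain-text files
#'
#' Serializes an `agb_study` as the same file set [read_study()] loads:
#' `censuses.csv`, `species.csv`, `phylogeny.nwk` (Newick), `elevation.csv`
#' (corner matrix, no header), `habitat.csv`, and `study.json` (config,
#' pooled height coefficients, truth record). Every CSV starts with one `#`
#' metadata line naming the package version and seed; no timestamps are
#' written, so identical studies serialize byte-identically.
#'
#' @param study An `agb_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "agb_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- sprintf("# agbdrivers study seed=%d", study$config$seed)
  write_csv_meta(study$censuses, file.path(dir, "censuses.csv"), meta)
  write_csv_meta(study$species, file.path(dir, "species.csv"), meta)
  write_csv_meta(study$landscape$quadrats, file.path(dir, "habitat.csv"), meta)
  ape::write.tree(study$phylogeny, file.path(dir, "phylogeny.nwk"))
  con <- file(file.path(dir, "elevation.csv"), "w")
  writeLines(meta, con)
  utils::write.table(study$landscape$elevation, con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  close(con)
  cfg <- unclass(study$config)
  cfg$null <- if (is.null(cfg$null)) NULL else unclass(cfg$null)
  truth <- study$truth
  jsonlite::write_json(
    list(config = cfg, pooled_height = as.list(study$pooled_height), truth = truth),
    file.path(dir, "study.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

write_csv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  writeLines(meta, con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

#' Read and validate a study directory
#'
#' Loads the file set written by [write_study()] and cross-validates it:
#' alive stems must satisfy the 1-cm inclusion rule, `(tree, stem, census)`
#' keys must be unique, every census species must be in the species table and
#' the phylogeny (error, naming offenders), and phylogeny tips absent from
#' the censuses are pruned with a message.
#'
#' @param dir Directory produced by [write_study()] (or hand-assembled with
#'   the same file names and schemas).
#' @param quiet Suppress messages.
#' @return An `agb_study`.
#' @export
read_study <- function(dir, quiet = FALSE) {
  need <- c("censuses.csv", "species.csv", "habitat.csv", "phylogeny.nwk",
            "elevation.csv", "study.json")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files) > 0) {
    stop("study directory is missing: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  censuses <- readr::read_csv(file.path(dir, "censuses.csv"), comment = "#",
                              show_col_types = FALSE)
  species <- readr::read_csv(file.path(dir, "species.csv"), comment = "#",
                             show_col_types = FALSE)
  quadrats <- readr::read_csv(file.path(dir, "habitat.csv"), comment = "#",
                              show_col_types = FALSE)
  elevation <- as.matrix(utils::read.csv(file.path(dir, "elevation.csv"),
                                         header = FALSE, comment.char = "#"))
  dimnames(elevation) <- NULL
  phylogeny <- ape::read.tree(file.path(dir, "phylogeny.nwk"))
  js <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)

  # --- validation ---
  bad_dbh <- censuses$status == "alive" & censuses$dbh < 1
  if (any(bad_dbh)) {
    off <- censuses[which(bad_dbh)[1], ]
    stop("alive stem below the 1 cm inclusion rule: tree ", off$tree_id,
         " stem ", off$stem_id, " census ", off$census, " (dbh = ", off$dbh, ")",
         call. = FALSE)
  }
  keys <- paste(censuses$tree_id, censuses$stem_id, censuses$census)
  if (anyDuplicated(keys)) {
    stop("duplicate (tree, stem, census) record: ", keys[anyDuplicated(keys)],
         call. = FALSE)
  }
  no_sp <- setdiff(unique(censuses$species), species$species)
  if (length(no_sp) > 0) {
    stop("census species absent from species table: ",
         paste(head(no_sp, 10), collapse = ", "), call. = FALSE)
  }
  no_tip <- setdiff(unique(censuses$species), phylogeny$tip.label)
  if (length(no_tip) > 0) {
    stop("census species absent from phylogeny: ",
         paste(head(no_tip, 10), collapse = ", "), call. = FALSE)
  }
  extra_tips <- setdiff(phylogeny$tip.label, unique(censuses$species))
  if (length(extra_tips) > 0) {
    phylogeny <- ape::drop.tip(phylogeny, extra_tips)
    if (!quiet) message("pruned ", length(extra_tips),
                        " phylogeny tip(s) not present in the censuses")
  }
  no_quad <- setdiff(unique(censuses$quadrat), quadrats$quadrat)
  if (length(no_quad) > 0) {
    stop("census quadrats absent from habitat map: ",
         paste(head(no_quad, 10), collapse = ", "), call. = FALSE)
  }

  config <- rebuild_config(js$config)
  pooled <- unlist(js$pooled_height)
  attr(species, "pooled_height") <- pooled
  structure(list(config = config, species = species, phylogeny = phylogeny,
                 pooled_height = pooled,
                 landscape = structure(list(elevation = elevation, quadrats = quadrats),
                                       class = "landscape"),
                 censuses = censuses,
                 truth = js$truth),
            class = "agb_study")
}

rebuild_config <- function(cfg) {
  cfg$habitat_fractions <- unlist(cfg$habitat_fractions)
  cfg$disturbance <- lapply(cfg$disturbance, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  cfg$growth <- lapply(cfg$growth, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(cfg$embedded_effects)) cfg$embedded_effects <- unlist(cfg$embedded_effects)
  if (!is.null(cfg$null)) {
    cfg$null <- null_spec(scheme = cfg$null$scheme,
                          n_iterations = cfg$null$n_iterations, seed = cfg$null$seed)
  }
  cfg$recruit_dbh <- unlist(cfg$recruit_dbh)
  do.call(sim_config, cfg[intersect(names(cfg), names(formals(sim_config)))])
}

#' Write pipeline result tables to a directory
#'
#' Emits the intermediate and final tables of a [run_pipeline()] result as
#' metadata-headed CSVs plus a JSON summary of the driver models (selected
#' subsets, AIC, R2, grouped importances). Deterministic: rerunning the same
#' study writes byte-identical files.
#'
#' @param pipeline An `agb_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "agb_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- sprintf("# agbdrivers pipeline seed=%d", pipeline$config$seed)
  write_csv_meta(pipeline$agb, file.path(dir, "agb.csv"), meta)
  write_csv_meta(pipeline$delta, file.path(dir, "delta_agb.csv"), meta)
  write_csv_meta(pipeline$topography, file.path(dir, "topography.csv"), meta)
  write_csv_meta(pipeline$wilcoxon, file.path(dir, "wilcoxon.csv"), meta)
  write_csv_meta(pipeline$profile, file.path(dir, "diversity.csv"), meta)
  write_csv_meta(pipeline$changes, file.path(dir, "diversity_changes.csv"), meta)
  write_csv_meta(pipeline$covariates, file.path(dir, "covariates.csv"), meta)
  coefs <- purrr::imap_dfr(pipeline$drivers$fits, function(f, nm) {
    dplyr::mutate(tidy(f), cell = nm, .before = 1)
  })
  write_csv_meta(coefs, file.path(dir, "driver_coefficients.csv"), meta)
  summ <- purrr::map(pipeline$drivers$fits, function(f) {
    list(stratum = f$stratum, interval = f$interval, n = f$n,
         selected = f$selected, aic = f$aic, r2 = f$r2,
         vif_dropped = f$vif_dropped$term,
         dimensions = setNames(as.list(f$dimensions$rel_importance),
                               f$dimensions$dimension))
  })
  jsonlite::write_json(list(seed = pipeline$config$seed, cells = summ),
                       file.path(dir, "drivers.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
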