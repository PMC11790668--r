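#' Quadrat-by-species abundance matrix for one census
#'
#' Counts alive stems at or above the diameter inclusion threshold. The
#' result is the standard community matrix consumed by vegan/picante-style
#' functions and by [ses_metric()] and [functional_dispersion()].
#'
#' @param census Stem table (one or more censuses).
#' @param which_census Census label to tabulate (default: the only one
#'   present; required when several are).
#' @param min_dbh Inclusion threshold in cm (default 1).
#' @param quadrats Optional quadrat ids to include as (possibly empty) rows.
#' @return Integer matrix, quadrats in rows, species in columns.
#' @export
community_matrix <- function(census, which_census = NULL, min_dbh = 1,
                             quadrats = NULL) {
  stopifnot(is.data.frame(census))
  labs <- unique(census$census)
  if (is.null(which_census)) {
    if (length(labs) > 1) stop("several censuses present; pass `which_census`", call. = FALSE)
    which_census <- labs
  }
  sub <- dplyr::filter(census, .data$census == which_census,
                       .data$status == "alive", .data$dbh >= min_dbh)
  if (is.null(quadrats)) quadrats <- sort(unique(census$quadrat))
  species <- sort(unique(census$species))
  m <- matrix(0L, length(quadrats), length(species),
              dimnames = list(quadrats, species))
  if (nrow(sub) > 0) {
    tab <- table(factor(sub$quadrat, levels = quadrats),
                 factor(sub$species, levels = species))
    m[] <- as.integer(tab)
  }
  m
}

#' Taxonomic diversity indices
#'
#' Shannon-Wiener `H = -sum(p log p)` (natural log), Simpson and Pielou
#' evenness `J = H / log(S)` per community. The Simpson index defaults to the
#' Gini-Simpson form `1 - sum(p^2)` so that, like `H` and `J`, larger means
#' more diverse; the raw dominance form `sum(p^2)` is available by argument.
#' `J` is undefined for monocultures and all three are undefined for empty
#' communities; both cases yield `NA`.
#'
#' @param comm Community matrix (quadrats x species), or a single count vector.
#' @param simpson `"gini"` (default) or `"dominance"`.
#' @return Tibble with `quadrat`, `richness`, `H`, `D`, `J`.
#' @export
taxonomic_indices <- function(comm, simpson = c("gini", "dominance")) {
  simpson <- match.arg(simpson)
  comm <- as_comm_matrix(comm)
  tot <- rowSums(comm)
  S <- rowSums(comm > 0)
  H <- suppressWarnings(vegan::diversity(comm, index = "shannon"))
  D <- suppressWarnings(vegan::diversity(comm, index = "simpson"))
  if (simpson == "dominance") D <- 1 - D
  H[tot == 0] <- NA_real_
  D[tot == 0] <- NA_real_
  J <- ifelse(S > 1, H / log(S), NA_real_)
  tibble::tibble(quadrat = rownames(comm), richness = as.integer(S),
                 H = unname(H), D = unname(D), J = unname(J))
}

#' Structural diversity indices
#'
#' Stand density `SD` (stems at or above the inclusion threshold) and the
#' coefficient of variation of diameter `CV_DBH = sigma / mu`, with `sigma`
#' the sample (n-1) standard deviation. `CV_DBH` is `NA` below two stems.
#'
#' @param census Stem table; alive stems with `dbh >= min_dbh` are used.
#' @param min_dbh Inclusion threshold, cm.
#' @param quadrats Optional quadrat ids to report (zero-stem rows included).
#' @return Tibble with `quadrat`, `census`, `SD`, `CV_DBH`.
#' @export
structural_indices <- function(census, min_dbh = 1, quadrats = NULL) {
  stopifnot(is.data.frame(census))
  if (is.null(quadrats)) quadrats <- sort(unique(census$quadrat))
  grid <- tidyr::expand_grid(quadrat = quadrats, census = sort(unique(census$census)))
  census |>
    dplyr::filter(.data$status == "alive", .data$dbh >= min_dbh) |>
    dplyr::group_by(.data$quadrat, .data$census) |>
    dplyr::summarise(SD = dplyr::n(),
                     CV_DBH = ifelse(dplyr::n() >= 2, sd(.data$dbh) / mean(.data$dbh),
                                     NA_real_),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("quadrat", "census")) |>
    dplyr::mutate(SD = dplyr::coalesce(.data$SD, 0L)) |>
    dplyr::arrange(.data$census, .data$quadrat)
}

#' Trait distance matrices: Gower and UPGMA-dendrogram cophenetic
#'
#' Builds the two species-by-species functional distance matrices used by the
#' functional-diversity indices: the Gower dissimilarity over wood density and
#' maximum height (range-scaled over the whole pool) and life form (simple
#' matching), all equally weighted; and the cophenetic distance on the UPGMA
#' (average-linkage) dendrogram of that Gower matrix, which is the distance
#' the trait analogues of MPD/MNTD are computed on.
#'
#' @param species Species table with complete `wd`, `hmax`, `life_form`.
#' @return List with symmetric matrices `gower` and `dendrogram`
#'   (species ids as dimnames).
#' @export
trait_distances <- function(species) {
  stopifnot(is.data.frame(species))
  req <- c("species", "wd", "hmax", "life_form")
  if (!all(req %in% names(species))) {
    stop("species table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- species$species[!complete.cases(species[, c("wd", "hmax", "life_form")])]
  if (length(bad) > 0) {
    stop("missing trait values for species: ", paste(head(bad, 10), collapse = ", "),
         "; impute upstream", call. = FALSE)
  }
  df <- data.frame(wd = species$wd, hmax = species$hmax,
                   life_form = factor(species$life_form))
  rownames(df) <- species$species
  g <- as.matrix(cluster::daisy(df, metric = "gower"))
  hc <- hclust(as.dist(g), method = "average")
  d <- as.matrix(cophenetic(hc))
  d <- d[rownames(g), colnames(g)]
  list(gower = g, dendrogram = d)
}

#' Functional dispersion and Rao's quadratic entropy
#'
#' `RaoQ = sum_i sum_j p_i p_j d_ij` is the expected trait distance between
#' two individuals drawn at random (with replacement) from the community.
#' `FDis` is the abundance-weighted mean distance of species to the
#' abundance-weighted community centroid in the principal-coordinate space of
#' the distance matrix; axes with non-positive eigenvalues are truncated.
#' Both are 0 for monocultures.
#'
#' @param comm Community matrix (quadrats x species) or a count vector named
#'   by species.
#' @param dist Species distance matrix covering all species in `comm`
#'   (typically the `gower` element of [trait_distances()]).
#' @return Tibble with `quadrat`, `FDis`, `RaoQ` (`NA` for empty communities).
#' @export
functional_dispersion <- function(comm, dist) {
  comm <- as_comm_matrix(comm)
  check_species_in_dist(colnames(comm), dist)
  D <- dist[colnames(comm), colnames(comm)]
  S <- ncol(D)
  # pool-level principal coordinates, negative axes truncated
  coords <- matrix(0, S, 1, dimnames = list(colnames(comm), NULL))
  if (S >= 2 && max(D) > 0) {
    pc <- suppressWarnings(cmdscale(D, k = S - 1, eig = TRUE))
    eig <- pc$eig[seq_len(ncol(pc$points))]
    keep <- eig > sqrt(.Machine$double.eps) * max(pc$eig)
    if (any(keep)) coords <- pc$points[, keep, drop = FALSE]
  }
  res <- purrr::map_dfr(seq_len(nrow(comm)), function(i) {
    x <- comm[i, ]
    tot <- sum(x)
    if (tot == 0) {
      return(tibble::tibble(FDis = NA_real_, RaoQ = NA_real_))
    }
    p <- x / tot
    rao <- drop(p %*% D %*% p)
    centroid <- drop(p %*% coords)
    dc <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
    tibble::tibble(FDis = sum(p * dc), RaoQ = rao)
  })
  dplyr::bind_cols(tibble::tibble(quadrat = rownames(comm)), res)
}

#' Interval change values of diversity indices
#'
#' Later-minus-earlier differences of every index column between the censuses
#' of each interval; missing values propagate to missing. Change columns are
#' prefixed `c` (`cH`, `cMPD`, ...), the field's usual notation.
#'
#' @param profile Per-quadrat, per-census index table (e.g. from
#'   [diversity_profile()]); all columns other than `quadrat` and `census`
#'   are differenced.
#' @param pairs List of `(from, to)` census pairs; defaults to consecutive.
#' @return Tibble `quadrat`, `interval`, `census_from`, `census_to`, plus one
#'   `c`-prefixed column per index.
#' @export
change_values <- function(profile, pairs = NULL) {
  stopifnot(is.data.frame(profile), all(c("quadrat", "census") %in% names(profile)))
  censuses <- sort(unique(profile$census))
  if (is.null(pairs)) {
    if (length(censuses) < 2) stop("need at least two censuses", call. = FALSE)
    pairs <- Map(c, censuses[-length(censuses)], censuses[-1])
  }
  idx_cols <- setdiff(names(profile), c("quadrat", "census", "richness"))
  purrr::imap_dfr(pairs, function(pr, i) {
    p1 <- dplyr::filter(profile, .data$census == pr[[1]])
    p2 <- dplyr::filter(profile, .data$census == pr[[2]])
    j <- dplyr::inner_join(p1, p2, by = "quadrat", suffix = c("_1", "_2"))
    out <- tibble::tibble(quadrat = j$quadrat, interval = i,
                          census_from = pr[[1]], census_to = pr[[2]])
    for (col in idx_cols) {
      out[[paste0("c", col)]] <- j[[paste0(col, "_2")]] - j[[paste0(col, "_1")]]
    }
    out
  })
}

# coerce count vector / data.frame to a quadrats x species matrix
as_comm_matrix <- function(comm) {
  if (is.matrix(comm)) {
    if (is.null(rownames(comm))) rownames(comm) <- paste0("site", seq_len(nrow(comm)))
    return(comm)
  }
  if (is.numeric(comm) && !is.null(names(comm))) {
    return(matrix(comm, 1, dimnames = list("site1", names(comm))))
  }
  if (is.data.frame(comm)) {
    m <- as.matrix(comm)
    if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
    return(m)
  }
  stop("`comm` must be a matrix, data frame, or named count vector", call. = FALSE)
}

check_species_in_dist <- function(species, dist) {
  if (!is.matrix(dist) || is.null(rownames(dist))) {
    stop("`dist` must be a matrix with species dimnames", call. = FALSE)
  }
  missing <- setdiff(species, rownames(dist))
  if (length(missing) > 0) {
    stop("species absent from distance matrix: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
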