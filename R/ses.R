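#' Null-model specification for standardized effect sizes
#'
#' @param scheme Randomization scheme. `"taxa-shuffle"` (default) shuffles
#'   species labels across the distance matrix, equivalent -- for the
#'   presence-based metrics used here -- to drawing random species sets of the
#'   observed richness from the pool. `"richness-swap"` uses the
#'   independent-swap algorithm, preserving both community richness and
#'   species occurrence frequencies across the whole community matrix.
#' @param n_iterations Number of null randomizations (default 999).
#' @param seed Integer seed for the null draws.
#' @return A list of class `null_spec`.
#' @export
null_spec <- function(scheme = c("taxa-shuffle", "richness-swap"),
                      n_iterations = 999, seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_iterations < 2) stop("`n_iterations` must be >= 2", call. = FALSE)
  structure(list(scheme = scheme, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)), class = "null_spec")
}

#' Standardized effect size of MPD or MNTD
#'
#' Computes the raw mean pairwise distance (MPD, mean over distinct species
#' pairs) or mean nearest-taxon distance (MNTD, mean over species of the
#' distance to the nearest other member) of each community on a species
#' distance matrix, then standardizes against a null distribution:
#' `SES = (observed - null mean) / null sd`. Positive SES means the community
#' is more dispersed than expected at its richness; `sign_flip = TRUE`
#' multiplies the SES by -1, the convention used for trait-dendrogram
#' distances so that larger values mean higher functional diversity.
#'
#' Communities of richness below two, and communities whose null distribution
#' is degenerate (null sd of 0, e.g. a community containing the whole pool
#' under taxa-shuffle), yield `NA` with the reason recorded.
#'
#' Metrics are presence-based by default (the community is its species set);
#' `weighted = TRUE` abundance-weights MPD by pairwise abundance products and
#' MNTD by species abundances.
#'
#' @param comm Community matrix (quadrats x species), or a named count vector.
#' @param dist Species distance matrix; must cover every species in `comm`.
#' @param metric `"MPD"` or `"MNTD"`.
#' @param null A [null_spec()].
#' @param sign_flip Multiply the SES by -1 (trait-metric convention).
#' @param weighted Abundance-weight the raw metric (default `FALSE`).
#' @return Tibble with `quadrat`, `richness`, `observed`, `null_mean`,
#'   `null_sd`, `ses`, `flag` (`"ok"`, `"richness<2"` or `"degenerate"`).
#' @export
ses_metric <- function(comm, dist, metric = c("MPD", "MNTD"), null = null_spec(),
                       sign_flip = FALSE, weighted = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(null, "null_spec"))
  comm <- as_comm_matrix(comm)
  check_species_in_dist(colnames(comm), dist)
  D <- dist[colnames(comm), colnames(comm)]
  S <- ncol(D)
  richness <- as.integer(rowSums(comm > 0))

  raw_fun <- if (metric == "MPD") raw_mpd else raw_mntd

  observed <- vapply(seq_len(nrow(comm)), function(i) {
    x <- comm[i, ]
    if (sum(x > 0) < 2) return(NA_real_)
    raw_fun(which(x > 0), D, if (weighted) x[x > 0] else NULL)
  }, numeric(1))

  if (null$scheme == "taxa-shuffle") {
    # Null distribution depends only on richness (and, if weighted, on the
    # abundance multiset -- approximated by permuting labels per community).
    nulls <- matrix(NA_real_, nrow(comm), 2)
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(null$seed)
    if (!weighted) {
      rs <- sort(unique(richness[richness >= 2]))
      memo <- lapply(rs, function(r) {
        draws <- vapply(seq_len(null$n_iterations), function(k) {
          raw_fun(sample.int(S, r), D, NULL)
        }, numeric(1))
        c(mean(draws), sd(draws))
      })
      names(memo) <- as.character(rs)
      for (i in seq_len(nrow(comm))) {
        if (richness[i] >= 2) nulls[i, ] <- memo[[as.character(richness[i])]]
      }
    } else {
      for (i in seq_len(nrow(comm))) {
        x <- comm[i, ]
        r <- sum(x > 0)
        if (r < 2) next
        ab <- x[x > 0]
        draws <- vapply(seq_len(null$n_iterations), function(k) {
          raw_fun(sample.int(S, r), D, ab)
        }, numeric(1))
        nulls[i, ] <- c(mean(draws), sd(draws))
      }
    }
  } else {
    nulls <- swap_null(comm, D, raw_fun, null, weighted)
  }

  null_mean <- nulls[, 1]
  null_sd <- nulls[, 2]
  ses <- (observed - null_mean) / null_sd
  degenerate <- !is.na(null_sd) & null_sd <= .Machine$double.eps^0.5
  ses[degenerate] <- NA_real_
  if (sign_flip) ses <- -ses
  tibble::tibble(
    quadrat = rownames(comm),
    richness = richness,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    flag = dplyr::case_when(richness < 2 ~ "richness<2",
                            degenerate ~ "degenerate",
                            TRUE ~ "ok")
  )
}

# mean pairwise distance of the species at `idx`; abundance-weighted if `ab`
# (weighting follows the picante convention: all individual pairs, including
# conspecific zero-distance pairs, weighted by abundance products)
raw_mpd <- function(idx, D, ab = NULL) {
  d <- D[idx, idx]
  if (is.null(ab)) {
    sum(d) / (length(idx) * (length(idx) - 1))
  } else {
    w <- outer(ab, ab)
    sum(w * d) / sum(w)
  }
}

# mean distance to nearest other community member
raw_mntd <- function(idx, D, ab = NULL) {
  d <- D[idx, idx]
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  if (is.null(ab)) mean(nearest) else sum(ab * nearest) / sum(ab)
}

# independent-swap null: metric recomputed on randomized occurrence matrices
swap_null <- function(comm, D, raw_fun, null, weighted) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(null$seed)
  draws <- array(NA_real_, c(nrow(comm), null$n_iterations))
  for (k in seq_len(null$n_iterations)) {
    rc <- picante::randomizeMatrix(comm, null.model = "independentswap")
    draws[, k] <- vapply(seq_len(nrow(rc)), function(i) {
      x <- rc[i, ]
      if (sum(x > 0) < 2) return(NA_real_)
      raw_fun(which(x > 0), D, if (weighted) x[x > 0] else NULL)
    }, numeric(1))
  }
  cbind(rowMeans(draws), apply(draws, 1, sd))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
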