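#' Rank-sum comparison of quadrat biomass between censuses
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum tests of per-quadrat AGB
#' between census pairs, overall and within habitat strata. Exact p-values
#' are used for small untied samples, otherwise the normal approximation with
#' tie and continuity corrections (the `stats::wilcox.test` defaults). A
#' paired signed-rank variant is available since quadrats are re-measured.
#'
#' @param agb Output of [quadrat_agb()]; an optional `habitat` column (or a
#'   `habitat_map` to join) enables per-stratum tests.
#' @param pairs List of `(from, to)` census pairs; defaults to consecutive.
#' @param habitat_map Optional `quadrat`/`habitat` table.
#' @param paired Use the paired signed-rank test instead (default `FALSE`).
#' @return Tibble: `stratum`, `census_from`, `census_to`, `n`, `statistic`,
#'   `p_value`, `stars`.
#' @export
wilcoxon_compare <- function(agb, pairs = NULL, habitat_map = NULL, paired = FALSE) {
  stopifnot(is.data.frame(agb))
  if (!is.null(habitat_map)) {
    agb <- dplyr::left_join(agb, dplyr::select(habitat_map, "quadrat", "habitat"),
                            by = "quadrat")
  }
  censuses <- sort(unique(agb$census))
  if (is.null(pairs)) pairs <- Map(c, censuses[-length(censuses)], censuses[-1])
  strata <- "whole"
  if ("habitat" %in% names(agb)) strata <- c("whole", sort(unique(as.character(agb$habitat))))
  purrr::map_dfr(strata, function(st) {
    sub <- if (st == "whole") agb else dplyr::filter(agb, .data$habitat == st)
    if (nrow(sub) == 0) stop("empty stratum: ", st, call. = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      x <- dplyr::filter(sub, .data$census == pr[[1]]) |> dplyr::arrange(.data$quadrat)
      y <- dplyr::filter(sub, .data$census == pr[[2]]) |> dplyr::arrange(.data$quadrat)
      if (nrow(x) < 2 || nrow(y) < 2) stop("fewer than 2 quadrats in stratum ", st, call. = FALSE)
      wt <- suppressWarnings(wilcox.test(y$agb, x$agb, paired = paired))
      tibble::tibble(stratum = st, census_from = pr[[1]], census_to = pr[[2]],
                     n = nrow(x), statistic = unname(wt$statistic),
                     p_value = wt$p.value, stars = p_stars(wt$p.value))
    })
  })
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Z-score model-frame columns
#'
#' Centers each selected column to mean 0 and scales it to sample standard
#' deviation 1. Zero-variance columns cannot be scaled and are dropped with a
#' warning (recorded in the `"dropped"` attribute). Scaling twice is
#' idempotent.
#'
#' @param data A data frame with at least 2 rows.
#' @param cols Columns to scale; default all numeric columns.
#' @return `data` with scaled columns; attribute `dropped` lists removals.
#' @export
standardize <- function(data, cols = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  dropped <- character(0)
  for (cl in cols) {
    s <- sd(data[[cl]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, cl)
      data[[cl]] <- NULL
    } else {
      data[[cl]] <- (data[[cl]] - mean(data[[cl]], na.rm = TRUE)) / s
    }
  }
  if (length(dropped) > 0) {
    warning("dropped zero-variance column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  attr(data, "dropped") <- dropped
  data
}

#' Variance inflation factors of a predictor set
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on all the others
#' (with intercept). Perfectly collinear predictors get `Inf`.
#'
#' @param data Data frame holding the predictors.
#' @param predictors Character vector of predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(data, predictors) {
  X <- as.matrix(data[, predictors, drop = FALSE])
  vapply(seq_along(predictors), function(j) {
    y <- X[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(predictors)
}

#' Iterative collinearity filter on VIF
#'
#' Repeatedly removes the single predictor with the highest variance
#' inflation factor until all remaining VIFs are at or below the threshold
#' (default 5). Perfect collinearity (infinite VIF) is removed first.
#'
#' @param data Data frame holding the predictors.
#' @param predictors Character vector of candidate predictors.
#' @param threshold VIF threshold (default 5).
#' @return List: `kept` (surviving predictors), `dropped` (tibble `term`,
#'   `vif` at removal), `vif` (final VIFs of survivors).
#' @export
vif_filter <- function(data, predictors, threshold = 5) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  kept <- predictors
  dropped <- tibble::tibble(term = character(0), vif = numeric(0))
  while (length(kept) >= 2) {
    v <- vif(data, kept)
    if (max(v) <= threshold) break
    worst <- which.max(v)  # ties: first, i.e. earliest column
    dropped <- dplyr::bind_rows(dropped,
                                tibble::tibble(term = kept[worst], vif = unname(v[worst])))
    kept <- kept[-worst]
  }
  final <- if (length(kept) >= 2) vif(data, kept) else setNames(rep(1, length(kept)), kept)
  list(kept = kept, dropped = dropped, vif = final)
}

# Gaussian AIC with estimated variance: intercept + k slopes + sigma^2
aic_gaussian <- function(rss, n, k) n * log(rss / n) + 2 * (k + 2)

#' Exhaustive lowest-AIC subset selection for a Gaussian linear model
#'
#' Fits an ordinary-least-squares Gaussian model for every non-empty
#' predictor subset and returns the one with the lowest Gaussian AIC
#' `n*log(RSS/n) + 2*(k+2)` (intercept and error variance counted as
#' parameters). Ties are broken toward fewer predictors, then
#' lexicographically. Subset size is capped at `n - 3` so the error variance
#' stays estimable. Above `max_exhaustive` predictors the search falls back
#' to bidirectional stepwise AIC (same criterion up to an additive constant),
#' with a message.
#'
#' @param data Model frame containing `response` and `predictors`.
#' @param response Response column name.
#' @param predictors Candidate predictor names.
#' @param max_exhaustive Largest predictor count still searched exhaustively
#'   (default 15).
#' @param max_size Optional cap on subset size (e.g. 12 to keep the
#'   downstream partitioning tractable).
#' @param keep_all Also return the full enumeration table (exhaustive mode).
#' @return List of class `best_subset`: `terms`, `aic`, `r2`, `fit` (an
#'   `lm`), `method`, and optionally `all_subsets`.
#' @export
best_subset_aic <- function(data, response, predictors, max_exhaustive = 15,
                            max_size = NULL, keep_all = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  n <- nrow(data)
  y <- data[[response]]
  p <- length(predictors)
  cap <- n - 3
  if (!is.null(max_size)) cap <- min(cap, max_size)
  if (cap < 1) stop("too few observations to fit any model", call. = FALSE)
  if (cap < p) message("subset size capped at ", cap, " predictors")

  if (p <= max_exhaustive) {
    X <- as.matrix(data[, predictors, drop = FALSE])
    best <- NULL
    best_aic <- Inf
    all_rows <- if (keep_all) vector("list", 0) else NULL
    # floor the RSS at numerical noise so an exact fit cannot be "improved"
    # by junk predictors through rounding error
    tss <- sum((y - mean(y))^2)
    rss_floor <- tss * 1e-12
    for (k in seq_len(min(p, cap))) {
      sets <- combn(p, k, simplify = FALSE)
      for (s in sets) {
        fit <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), y)
        rss <- max(sum(fit$residuals^2), rss_floor)
        a <- aic_gaussian(rss, n, k)
        if (keep_all) {
          all_rows[[length(all_rows) + 1]] <-
            tibble::tibble(terms = paste(predictors[s], collapse = "+"), k = k, aic = a)
        }
        # strict improvement: size-ascending, lexicographic enumeration makes
        # "first encountered" the parsimony + lexicographic tie-break
        if (a < best_aic - 1e-9) {
          best_aic <- a
          best <- s
        }
      }
    }
    terms <- predictors[best]
    method <- "exhaustive"
    all_subsets <- if (keep_all) dplyr::bind_rows(all_rows) else NULL
  } else {
    message("more than ", max_exhaustive,
            " predictors; falling back to bidirectional stepwise AIC")
    df <- data[, c(response, predictors)]
    full_rhs <- paste(predictors, collapse = " + ")
    null_fit <- lm(stats::reformulate("1", response), data = df)
    sc <- list(lower = stats::reformulate("1", response),
               upper = stats::reformulate(predictors, response))
    step_fit <- stats::step(null_fit, scope = sc, direction = "both", trace = 0)
    terms <- setdiff(names(coef(step_fit)), "(Intercept)")
    if (length(terms) == 0) terms <- predictors[1]  # keep a non-empty model
    method <- "stepwise"
    all_subsets <- NULL
  }
  fit <- lm(stats::reformulate(terms, response), data = data)
  rss <- sum(stats::residuals(fit)^2)
  out <- list(terms = terms,
              aic = aic_gaussian(rss, n, length(terms)),
              r2 = summary(fit)$r.squared,
              fit = fit, n = n, method = method)
  if (keep_all) out$all_subsets <- all_subsets
  structure(out, class = "best_subset")
}

#' Hierarchical partitioning of regression R-squared
#'
#' Chevan-Sutherland goodness-of-fit partitioning: the independent
#' contribution of predictor `j` is the average, over hierarchy levels
#' `h = 0..k-1`, of the mean increase in R2 from adding `j` to each size-`h`
#' subset not containing it. Independent contributions sum exactly to the
#' full-model R2; joint contributions (a predictor's one-variable R2 minus
#' its independent contribution) may be negative and are reported as
#' diagnostics. Relative importance is the independent contribution as a
#' percentage of their sum.
#'
#' @param data Model frame.
#' @param response Response column name.
#' @param predictors Predictors to partition over (`k <= 12`).
#' @return Tibble `term`, `independent`, `joint`, `rel_importance`; attribute
#'   `full_r2` holds the full-model R2.
#' @export
hierarchical_partition <- function(data, response, predictors) {
  k <- length(predictors)
  if (k < 1) stop("need at least one predictor", call. = FALSE)
  if (k > 12) {
    stop("hierarchical partitioning over ", k,
         " predictors is combinatorially infeasible; select 12 or fewer",
         call. = FALSE)
  }
  y <- data[[response]]
  X <- as.matrix(data[, predictors, drop = FALSE])
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  n_masks <- bitwShiftL(1L, k)
  r2 <- numeric(n_masks)  # r2[mask + 1]
  for (mask in seq_len(n_masks - 1)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    fit <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), y)
    r2[mask + 1] <- 1 - sum(fit$residuals^2) / tss
  }
  sizes <- vapply(0:(n_masks - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L),
                  integer(1))
  indep <- vapply(seq_len(k), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    masks_without <- which(bitwAnd(0:(n_masks - 1), bit) == 0L) - 1L
    inc <- r2[masks_without + bit + 1L] - r2[masks_without + 1L]
    lvl <- sizes[masks_without + 1L]
    mean(tapply(inc, lvl, mean))  # average of per-level means
  }, numeric(1))
  joint <- r2[bitwShiftL(1L, seq_len(k) - 1L) + 1L] - indep
  out <- tibble::tibble(
    term = predictors,
    independent = indep,
    joint = joint,
    rel_importance = 100 * indep / sum(indep)
  )
  attr(out, "full_r2") <- r2[n_masks]
  out
}

#' Default mapping of covariates to diversity dimensions
#'
#' Maps the standard covariate names (initial and change values alike) to the
#' five dimensions used when grouping relative importance: taxonomic,
#' structural, phylogenetic, functional, topographic.
#'
#' @return Tibble `term`, `dimension`.
#' @export
dimension_map <- function() {
  base <- tibble::tribble(
    ~term, ~dimension,
    "H", "taxonomic", "D", "taxonomic", "J", "taxonomic",
    "SD", "structural", "CV_DBH", "structural",
    "MPD", "phylogenetic", "MNTD", "phylogenetic",
    "traitMPD", "functional", "traitMNTD", "functional",
    "FDis", "functional", "RaoQ", "functional",
    "elevation", "topographic", "slope", "topographic",
    "aspect", "topographic", "convexity", "topographic"
  )
  changes <- base |>
    dplyr::filter(.data$dimension != "topographic") |>
    dplyr::mutate(term = paste0("c", .data$term))
  dplyr::bind_rows(base, changes)
}

#' Group per-predictor relative importance into diversity dimensions
#'
#' @param importance Tibble with `term` and `rel_importance` (e.g. from
#'   [hierarchical_partition()] or a `driver_fit`).
#' @param grouping Tibble `term`/`dimension`; defaults to [dimension_map()].
#' @return Tibble `dimension`, `rel_importance` summing to 100.
#' @export
dimension_importance <- function(importance, grouping = dimension_map()) {
  if (inherits(importance, "driver_fit")) importance <- importance$hp
  unmapped <- setdiff(importance$term, grouping$term)
  if (length(unmapped) > 0) {
    stop("predictor(s) not mapped to a dimension: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  importance |>
    dplyr::left_join(grouping, by = "term") |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(rel_importance = sum(.data$rel_importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$rel_importance))
}

#' Full driver analysis of biomass change, per interval and stratum
#'
#' For each requested interval x stratum cell, assembles the model frame
#' (biomass change as response; topographic, initial-diversity and
#' change-diversity covariates as predictors), listwise-deletes incomplete
#' quadrats, z-scores everything, filters collinear predictors at the VIF
#' threshold, selects the lowest-AIC predictor subset, and partitions the
#' selected model's R2 into per-predictor and per-dimension relative
#' importance.
#'
#' @param covariates Per-quadrat covariate table with columns `quadrat`,
#'   `habitat`, `interval`, the response, and predictor columns (see
#'   [diversity_covariates()]).
#' @param response Response column (default `"d_agb"`).
#' @param predictors Predictor columns; defaults to every covariate known to
#'   [dimension_map()] that is present.
#' @param strata Strata to analyse; `"whole"` plus habitat labels.
#' @param intervals Intervals to analyse; default all present.
#' @param vif_threshold VIF threshold (default 5).
#' @param max_exhaustive,max_size Passed to [best_subset_aic()]; `max_size`
#'   defaults to 12 so the partitioning stays tractable.
#' @param min_n Minimum quadrats per cell; smaller cells are skipped with a
#'   warning (default 10).
#' @param grouping Dimension map for grouped importance.
#' @return List of class `driver_analysis`: `fits` (list of `driver_fit`) and
#'   `summary` (one row per cell).
#' @export
run_driver_analysis <- function(covariates, response = "d_agb", predictors = NULL,
                                strata = NULL, intervals = NULL,
                                vif_threshold = 5, max_exhaustive = 15,
                                max_size = 12, min_n = 10,
                                grouping = dimension_map()) {
  stopifnot(is.data.frame(covariates), response %in% names(covariates))
  if (is.null(predictors)) {
    predictors <- intersect(dimension_map()$term, names(covariates))
  }
  if (is.null(intervals)) intervals <- sort(unique(covariates$interval))
  if (is.null(strata)) {
    strata <- "whole"
    if ("habitat" %in% names(covariates)) {
      strata <- c("whole", sort(unique(as.character(covariates$habitat))))
    }
  }
  fits <- list()
  for (iv in intervals) {
    for (st in strata) {
      cell <- dplyr::filter(covariates, .data$interval == iv)
      if (st != "whole") cell <- dplyr::filter(cell, .data$habitat == st)
      fit <- driver_cell(cell, response, predictors, stratum = st, interval = iv,
                         vif_threshold = vif_threshold,
                         max_exhaustive = max_exhaustive, max_size = max_size,
                         min_n = min_n, grouping = grouping)
      if (!is.null(fit)) fits[[paste0("interval", iv, "_", st)]] <- fit
    }
  }
  summary <- purrr::map_dfr(fits, glance.driver_fit)
  structure(list(fits = fits, summary = summary), class = "driver_analysis")
}

# one interval x stratum model cell
driver_cell <- function(cell, response, predictors, stratum, interval,
                        vif_threshold, max_exhaustive, max_size, min_n, grouping) {
  keep_cols <- c(response, predictors)
  cc <- complete.cases(cell[, keep_cols])
  n_dropped <- sum(!cc)
  cell <- cell[cc, , drop = FALSE]
  if (nrow(cell) < min_n) {
    warning("stratum ", stratum, ", interval ", interval, ": only ", nrow(cell),
            " complete quadrats (< ", min_n, "), skipped", call. = FALSE)
    return(NULL)
  }
  scaled <- suppressWarnings(standardize(cell, cols = keep_cols))
  preds <- intersect(predictors, names(scaled))
  vf <- vif_filter(scaled, preds, threshold = vif_threshold)
  bs <- best_subset_aic(scaled, response, vf$kept,
                        max_exhaustive = max_exhaustive, max_size = max_size)
  hp <- hierarchical_partition(scaled, response, bs$terms)
  dims <- dimension_importance(hp, grouping)
  sm <- summary(bs$fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4], stars = p_stars(sm[, 4])
  ) |> dplyr::filter(.data$term != "(Intercept)")
  structure(list(
    stratum = stratum, interval = interval,
    n = nrow(cell), n_dropped_na = n_dropped,
    candidates = preds, vif_dropped = vf$dropped, vif = vf$vif,
    selected = bs$terms, aic = bs$aic, r2 = bs$r2, method = bs$method,
    coefficients = coefs, hp = hp, dimensions = dims, fit = bs$fit
  ), class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat("Driver model -- stratum ", x$stratum, ", interval ", x$interval,
      " (n = ", x$n, ")\n", sep = "")
  cat("selected (AIC = ", round(x$aic, 2), ", R2 = ", round(x$r2, 3), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  print(dplyr::left_join(x$coefficients,
                         dplyr::select(x$hp, "term", "rel_importance"),
                         by = "term"), ...)
  cat("dimension importance:\n")
  print(x$dimensions, ...)
  invisible(x)
}

#' @export
print.driver_analysis <- function(x, ...) {
  cat("Driver analysis over", length(x$fits), "model cells\n")
  print(x$summary, ...)
  invisible(x)
}
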