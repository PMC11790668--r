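make_agb <- function(v1, v2, quadrats = paste0("q", seq_along(v1))) {
  dplyr::bind_rows(
    tibble::tibble(quadrat = quadrats, census = 1L, agb = v1),
    tibble::tibble(quadrat = quadrats, census = 2L, agb = v2)
  )
}

test_that("rank-sum comparison matches exact small-sample enumeration", {
  # clearly separated samples: U = 0, exact two-sided p for n = 3,3 is 0.1
  agb <- make_agb(c(1, 2, 3), c(10, 11, 12))
  got <- wilcoxon_compare(agb)
  expect_equal(got$p_value, 0.1, tolerance = 1e-12)
  expect_equal(got$stars, "")
  # identical samples: no shift
  same <- wilcoxon_compare(make_agb(c(5, 6, 7, 8), c(5, 6, 7, 8)))
  expect_gte(same$p_value, 0.99)
  # invariant to adding a constant to both samples
  shifted <- wilcoxon_compare(make_agb(c(1, 2, 3) + 50, c(10, 11, 12) + 50))
  expect_equal(shifted$p_value, got$p_value)
})

test_that("rank-sum comparison stratifies by habitat", {
  agb <- make_agb(1:8, 8:1)
  map <- tibble::tibble(quadrat = paste0("q", 1:8),
                        habitat = rep(c("H1", "H2"), each = 4))
  got <- wilcoxon_compare(agb, habitat_map = map)
  expect_setequal(got$stratum, c("whole", "H1", "H2"))
  expect_equal(got$n[got$stratum == "H1"], 4)
})

test_that("standardization centers, scales, drops constants, idempotent", {
  df <- tibble::tibble(a = rnorm(20, 5, 3), b = runif(20), k = 7)
  expect_warning(out <- standardize(df), "zero-variance")
  expect_false("k" %in% names(out))
  expect_lt(abs(mean(out$a)), 1e-12)
  expect_lt(abs(sd(out$a) - 1), 1e-12)
  out2 <- standardize(out)
  expect_equal(out2$a, out$a, tolerance = 1e-12)
  expect_error(standardize(df[1, ]), "2 rows")
})

test_that("VIF filtering removes collinear predictors until all pass", {
  set.seed(21)
  n <- 60
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  df$x3 <- df$x1 + df$x2 + rnorm(n, 0, 0.01)  # near-perfect trio
  df$x4 <- df$x1                               # exact duplicate
  vf <- vif_filter(df, c("x1", "x2", "x3", "x4"), threshold = 5)
  expect_true(all(vf$vif <= 5))
  expect_true(length(vf$kept) < 4)
  # duplicate handled: exactly one of x1/x4 survives
  expect_equal(sum(c("x1", "x4") %in% vf$kept), 1)
  # predictors orthogonal to each other and the intercept: VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  ortho <- tibble::as_tibble(setNames(as.data.frame(Q), c("o1", "o2", "o3")))
  vo <- vif_filter(ortho, c("o1", "o2", "o3"))
  expect_equal(length(vo$kept), 3)
  expect_equal(unname(vo$vif), rep(1, 3), tolerance = 1e-8)
})

test_that("VIF values agree with car's implementation", {
  skip_if_not_installed("car")
  set.seed(31)
  df <- random_frame(50, 4, seed = 31)
  df$x5 <- df$x1 * 0.8 + rnorm(50, 0, 0.4)
  preds <- paste0("x", 1:5)
  ours <- vif(df, preds)
  fit <- stats::lm(y ~ ., data = df)
  theirs <- car::vif(fit)
  expect_equal(unname(ours), unname(theirs[preds]), tolerance = 1e-8)
})

test_that("exhaustive subset selection finds the AIC optimum", {
  # noise-free signal: y = x1 exactly, x2 pure noise
  set.seed(41)
  df <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100))
  df$y <- df$x1
  bs <- best_subset_aic(df, "y", c("x1", "x2"))
  expect_equal(bs$terms, "x1")
  # single predictor frame
  one <- best_subset_aic(df, "y", "x1")
  expect_equal(one$terms, "x1")
  # 5-predictor frame: selected AIC <= every enumerated subset (oracle)
  df5 <- random_frame(60, 5, seed = 42, betas = c(1, 0.5, 0, 0, -0.8))
  bs5 <- best_subset_aic(df5, "y", paste0("x", 1:5), keep_all = TRUE)
  expect_equal(nrow(bs5$all_subsets), 31)
  expect_lte(bs5$aic, min(bs5$all_subsets$aic) + 1e-9)
  # independent oracle: refit every subset with lm
  preds <- paste0("x", 1:5)
  aics <- sapply(seq_len(31), function(i) {
    subs <- strsplit(bs5$all_subsets$terms[i], "\\+")[[1]]
    oracle_aic(stats::lm(stats::reformulate(subs, "y"), data = df5))
  })
  expect_equal(min(aics), bs5$aic, tolerance = 1e-9)
})

test_that("stepwise fallback engages above the exhaustive cap", {
  df <- random_frame(80, 6, seed = 5, betas = c(2, 0, 0, 0, 0, 0))
  expect_message(bs <- best_subset_aic(df, "y", paste0("x", 1:6),
                                       max_exhaustive = 4), "stepwise")
  expect_true("x1" %in% bs$terms)
})

test_that("hierarchical partitioning satisfies its identities", {
  # k = 1: independent contribution is the R2 itself
  df <- random_frame(50, 1, seed = 6, betas = 1)
  hp1 <- hierarchical_partition(df, "y", "x1")
  expect_equal(hp1$independent, attr(hp1, "full_r2"), tolerance = 1e-12)
  expect_equal(hp1$rel_importance, 100)
  # orthogonal predictors with equal marginal R2 split importance 50/50
  n <- 64
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  dfo <- tibble::tibble(x1 = Q[, 1], x2 = Q[, 2])
  dfo$y <- dfo$x1 + dfo$x2
  hpo <- hierarchical_partition(dfo, "y", c("x1", "x2"))
  expect_equal(hpo$rel_importance, c(50, 50), tolerance = 1e-8)
  # identity: contributions sum to the full-model R2
  df4 <- random_frame(40, 4, seed = 7)
  hp4 <- hierarchical_partition(df4, "y", paste0("x", 1:4))
  expect_equal(sum(hp4$independent), attr(hp4, "full_r2"), tolerance = 1e-10)
  # invariant to predictor order
  hp4r <- hierarchical_partition(df4, "y", paste0("x", 4:1))
  expect_equal(hp4r$independent[match(hp4$term, hp4r$term)], hp4$independent,
               tolerance = 1e-10)
  expect_error(hierarchical_partition(df4, "y", rep(paste0("x", 1:4), 4)),
               "12 or fewer")
})

test_that("level averaging equals averaging over all predictor orderings", {
  for (k in c(3, 5)) {
    df <- random_frame(35, k, seed = 100 + k)
    hp <- hierarchical_partition(df, "y", paste0("x", seq_len(k)))
    oracle <- oracle_hp_orderings(df, "y", paste0("x", seq_len(k)))
    expect_equal(hp$independent, unname(oracle[hp$term]), tolerance = 1e-10)
  }
})

test_that("dimension importance groups and validates terms", {
  hp <- tibble::tibble(term = c("SD", "cSD", "CV_DBH", "cCV_DBH"),
                       rel_importance = c(10, 20, 30, 40))
  got <- dimension_importance(hp)
  expect_equal(got$dimension, "structural")
  expect_equal(got$rel_importance, 100)
  hp2 <- tibble::tibble(term = c("MPD", "FDis"), rel_importance = c(30, 70))
  got2 <- dimension_importance(hp2)
  expect_equal(got2$rel_importance[got2$dimension == "functional"], 70)
  expect_equal(sum(got2$rel_importance), 100)
  expect_error(dimension_importance(tibble::tibble(term = "mystery",
                                                   rel_importance = 100)),
               "mystery")
})

test_that("the driver orchestrator emits one fit per interval-stratum cell", {
  set.seed(9)
  n <- 40
  cov <- tidyr::expand_grid(interval = 1:2, quadrat = paste0("q", 1:n)) |>
    dplyr::mutate(habitat = rep(rep(c("H1", "H2"), each = n / 2), 2),
                  elevation = rnorm(2 * n), slope = rnorm(2 * n),
                  H = rnorm(2 * n), SD = rnorm(2 * n), MPD = rnorm(2 * n),
                  d_agb = 0.8 * MPD + rnorm(2 * n, 0, 0.5))
  res <- run_driver_analysis(cov, predictors = c("elevation", "slope", "H", "SD", "MPD"))
  expect_length(res$fits, 6)  # 2 intervals x {whole, H1, H2}
  expect_true(all(vapply(res$fits, function(f) "MPD" %in% f$selected, logical(1))))
  est <- vapply(res$fits, function(f)
    f$coefficients$estimate[f$coefficients$term == "MPD"], numeric(1))
  expect_true(all(est > 0))
  # small strata are skipped with a warning
  cov_small <- dplyr::filter(cov, !(habitat == "H2" & quadrat %in% paste0("q", 21:35)))
  expect_warning(res2 <- run_driver_analysis(cov_small,
                                             predictors = c("elevation", "H", "MPD")),
                 "skipped")
  expect_length(res2$fits, 4)
  # tidy/glance surfaces
  td <- tidy(res$fits[[1]])
  expect_true(all(c("estimate", "rel_importance", "dimension") %in% names(td)))
  expect_equal(nrow(glance(res)), 6)
})
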