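test_that("height allometry follows a*D^b*CF and rejects bad inputs", {
  expect_equal(estimate_height(1, a = 3, b = 0.5), 3.0)
  expect_equal(estimate_height(10, a = 2, b = 0.5, cf = 1.05),
               2 * sqrt(10) * 1.05, tolerance = 1e-12)
  # monotone increasing in D
  d <- sort(runif(20, 1, 80))
  expect_true(all(diff(estimate_height(d, 1.5, 0.6, 1.02)) > 0))
  expect_error(estimate_height(-1, 1, 1), "positive")
  expect_error(estimate_height(10, a = 0, b = 1), "positive")
})

test_that("stem biomass allometry matches closed forms and is homogeneous", {
  expect_equal(estimate_stem_agb(1, 1, 1), 0.0673)
  expect_equal(estimate_stem_agb(10, 0.5, 10),
               0.0673 * 500^0.976, tolerance = 1e-12)
  # doubling WD multiplies AGB by 2^0.976
  expect_equal(estimate_stem_agb(7, 0.8, 12) * 2^0.976,
               estimate_stem_agb(7, 1.6, 12), tolerance = 1e-12)
  expect_error(estimate_stem_agb(10, -0.5, 10), "positive")
})

test_that("wood density imputation walks genus, family, then pool", {
  sp <- tibble::tibble(
    species = paste0("s", 1:6),
    genus = c("g1", "g1", "g1", "g2", "g4", "g3"),
    family = c("f1", "f1", "f1", "f1", "f1", "f2"),
    wd = c(0.4, 0.6, NA, 0.3, NA, NA)
  )
  # s6 is alone in genus g3 and family f2 -> pool-wide mean, warned
  expect_warning(out <- impute_wood_density(sp), "pool-wide")
  expect_equal(out$wd[3], 0.5)              # congeners 0.4, 0.6
  expect_equal(out$wd_source[3], "genus")
  expect_equal(out$wd[5], mean(c(0.4, 0.6, 0.3)))  # family fallback
  expect_equal(out$wd_source[5], "family")
  expect_equal(out$wd[6], mean(c(0.4, 0.6, 0.3)))
  expect_equal(out$wd_source[6], "pool")
  expect_true(all(!is.na(out$wd)))
  expect_error(impute_wood_density(dplyr::mutate(sp, wd = NA_real_)), "no observed")
})

test_that("family fallback averages confamilials", {
  sp <- tibble::tibble(
    species = paste0("s", 1:4),
    genus = c("g1", "g2", "g3", "g4"),
    family = "f1",
    wd = c(0.3, 0.5, 0.7, NA)
  )
  out <- impute_wood_density(sp)
  expect_equal(out$wd[4], 0.5)
})

make_species <- function(ids, wd = 0.5, a = 2, b = 0.5, cf = 1) {
  tibble::tibble(species = ids, genus = "g", family = "f",
                 wd = wd, hmax = 20, life_form = "evergreen broad-leaved",
                 a = a, b = b, cf = cf)
}

test_that("quadrat AGB sums alive stems and converts units correctly", {
  sp <- make_species("s1")
  cns <- tibble::tibble(tree_id = c("t1", "t1", "t2"), stem_id = c(1L, 2L, 1L),
                        species = "s1", quadrat = "q1",
                        dbh = c(10, 5, 20), census = 1L, status = "alive")
  got <- quadrat_agb(cns, sp, quadrat_area = 400, quiet = TRUE)
  # oracle: naive per-stem loop, kg -> Mg/ha
  kg <- sum(sapply(c(10, 5, 20), function(d) {
    estimate_stem_agb(d, 0.5, estimate_height(d, 2, 0.5, 1))
  }))
  expect_equal(got$agb, kg / 1000 * 10000 / 400, tolerance = 1e-12)
  # both stems of the multi-stem tree t1 counted
  one_stem <- quadrat_agb(cns[c(1, 3), ], sp, quadrat_area = 400, quiet = TRUE)
  expect_lt(one_stem$agb, got$agb)
})

test_that("dead stems and empty quadrats contribute zero", {
  sp <- make_species("s1")
  cns <- tibble::tibble(tree_id = c("t1", "t2"), stem_id = 1L, species = "s1",
                        quadrat = c("q1", "q2"), dbh = c(10, 30), census = 1L,
                        status = c("alive", "dead"))
  got <- quadrat_agb(cns, sp, quadrat_area = 400, quadrats = c("q1", "q2", "q3"),
                     quiet = TRUE)
  expect_equal(got$agb[got$quadrat == "q2"], 0)   # dead only
  expect_equal(got$agb[got$quadrat == "q3"], 0)   # empty
  expect_gt(got$agb[got$quadrat == "q1"], 0)
})

test_that("unknown species and missing wood density are keyed errors", {
  sp <- make_species("s1")
  cns <- tibble::tibble(tree_id = "t1", stem_id = 1L, species = "s2",
                        quadrat = "q1", dbh = 10, census = 1L, status = "alive")
  expect_error(quadrat_agb(cns, sp, quiet = TRUE), "s2")
  cns$species <- "s1"
  sp_na <- dplyr::mutate(sp, wd = NA_real_)
  expect_error(quadrat_agb(cns, sp_na, quiet = TRUE), "impute_wood_density")
})

test_that("pooled height coefficients are used and reported for unfitted species", {
  sp <- make_species("s1", a = NA_real_, b = NA_real_, cf = NA_real_)
  cns <- tibble::tibble(tree_id = "t1", stem_id = 1L, species = "s1",
                        quadrat = "q1", dbh = 10, census = 1L, status = "alive")
  expect_message(got <- quadrat_agb(cns, sp, quadrat_area = 400,
                                    pooled = c(a = 2, b = 0.5, cf = 1)),
                 "pooled")
  kg <- estimate_stem_agb(10, 0.5, estimate_height(10, 2, 0.5, 1))
  expect_equal(got$agb, kg / 1000 * 25, tolerance = 1e-12)
})

test_that("delta AGB is later-minus-earlier, telescopes, and pairs censuses", {
  agb <- tidyr::expand_grid(quadrat = c("q1", "q2"), census = 1:3) |>
    dplyr::mutate(agb = c(204.84, 178.33, 183.10, 100, 90, 95))
  d <- delta_agb(agb)
  expect_equal(nrow(d), 4)                     # 2 quadrats x 2 intervals
  expect_equal(sort(unique(d$interval)), 1:2)
  expect_equal(d$d_agb[d$quadrat == "q1" & d$interval == 1], -26.51)
  # telescoping: (c1 -> c3) = sum of consecutive intervals
  d13 <- delta_agb(agb, pairs = list(c(1, 3)))
  sums <- d |> dplyr::group_by(quadrat) |> dplyr::summarise(s = sum(d_agb))
  expect_equal(d13$d_agb, sums$s[match(d13$quadrat, sums$quadrat)], tolerance = 1e-12)
  # identical censuses -> zero change
  agb0 <- dplyr::mutate(agb, agb = 7)
  expect_true(all(delta_agb(agb0)$d_agb == 0))
  # missing quadrat is a keyed error
  expect_error(delta_agb(agb[-1, ]), "q1")
})
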