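test_that("species pool has nested taxonomy, traits, and a matching phylogeny", {
  pool <- simulate_species_pool(160, seed = 7)
  sp <- pool$species
  expect_equal(nrow(sp), 160)
  expect_equal(ape::Ntip(pool$phylogeny), 160)
  expect_setequal(pool$phylogeny$tip.label, sp$species)
  # withheld wood-density fraction matches the configured default
  expect_equal(mean(is.na(sp$wd)), round(0.149 * 160) / 160, tolerance = 1e-12)
  # lognormal wood density around 0.55
  expect_gt(median(sp$wd, na.rm = TRUE), 0.4)
  expect_lt(median(sp$wd, na.rm = TRUE), 0.7)
  # height coefficients either complete per species or absent (pooled)
  expect_true(all(is.na(sp$a) == is.na(sp$b)))
  # habitat affinities are proper weights
  expect_equal(rowSums(sp[, c("aff_H1", "aff_H2", "aff_H3")]), rep(1, 160),
               tolerance = 1e-12)
  # minimal pool
  tiny <- simulate_species_pool(2, seed = 1)
  expect_equal(ape::Ntip(tiny$phylogeny), 2)
  expect_setequal(tiny$phylogeny$tip.label, tiny$species$species)
  expect_error(simulate_species_pool(1), ">= 2")
})

test_that("pool simulation is a deterministic function of the seed", {
  a <- simulate_species_pool(40, seed = 3)
  b <- simulate_species_pool(40, seed = 3)
  expect_identical(a$species, b$species)
  expect_identical(ape::write.tree(a$phylogeny), ape::write.tree(b$phylogeny))
  c2 <- simulate_species_pool(40, seed = 4)
  expect_false(identical(a$species$wd, c2$species$wd))
})

test_that("landscape realizes the configured habitat counts exactly", {
  land <- simulate_landscape(sim_config(seed = 5))
  counts <- table(land$quadrats$habitat)
  expect_equal(unname(c(counts["H1"], counts["H2"], counts["H3"])),
               c(50, 45, 25))
  expect_equal(dim(land$elevation), c(13, 11))
  # valley in the middle: mid rows lower than edge rows
  expect_lt(mean(land$elevation[6:7, ]), mean(land$elevation[c(1, 13), ]))
  # determinism
  land2 <- simulate_landscape(sim_config(seed = 5))
  expect_identical(land, land2)
})

frozen_config <- function(seed = 2) {
  sim_config(n_species = 20, plot_cols = 3, plot_rows = 3, mean_stems = 15,
             background_mortality = 0, recruitment_rate = 0,
             growth = list(dbh_increment_mean = 0, sd = 0),
             disturbance = list(mortality_base = 0),
             null = null_spec(n_iterations = 49, seed = seed), seed = seed)
}

test_that("frozen dynamics reproduce census 1 exactly with zero biomass change", {
  study <- simulate_study(frozen_config())
  c1 <- dplyr::filter(study$censuses, census == 1) |> dplyr::select(-census)
  c2 <- dplyr::filter(study$censuses, census == 2) |> dplyr::select(-census)
  expect_equal(dplyr::arrange(c1, tree_id, stem_id),
               dplyr::arrange(c2, tree_id, stem_id))
  sp <- suppressWarnings(suppressMessages(impute_wood_density(study$species)))
  agb <- quadrat_agb(study$censuses, sp, quiet = TRUE)
  expect_true(all(abs(delta_agb(agb)$d_agb) < 1e-12))
})

test_that("demographic bookkeeping: no resurrection, no shrinkage, recruits small", {
  study <- simulate_study(light_config(seed = 11))
  cs <- study$censuses
  key <- function(d) paste(d$tree_id, d$stem_id)
  for (t in 1:2) {
    alive_t <- dplyr::filter(cs, census == t, status == "alive")
    alive_t1 <- dplyr::filter(cs, census == t + 1, status == "alive")
    recruits <- dplyr::filter(alive_t1, !(key(alive_t1) %in% key(alive_t)))
    survivors <- dplyr::filter(alive_t1, key(alive_t1) %in% key(alive_t))
    # alive at t+1 is a subset of alive-at-t plus new recruits
    expect_true(all(recruits$dbh <= 2.4 + 1e-9))
    # growth is non-negative
    m <- match(key(survivors), key(alive_t))
    expect_true(all(survivors$dbh >= alive_t$dbh[m] - 1e-9))
    # dead stems never come back
    dead_t <- dplyr::filter(cs, census == t, status == "dead")
    expect_false(any(key(alive_t1) %in% key(dead_t)))
  }
  # the study is bit-identical under the same config
  study2 <- simulate_study(light_config(seed = 11))
  expect_identical(study$censuses, study2$censuses)
  expect_identical(study$landscape, study2$landscape)
})

test_that("size-biased disturbance kills larger stems than survive", {
  cfg <- light_config(seed = 13,
                      disturbance = list(interval_index = 1, mortality_base = 0.2,
                                         size_bias_exponent = 1,
                                         habitat_weights = c(H1 = 1, H2 = 1, H3 = 1)))
  study <- simulate_study(cfg)
  c1 <- dplyr::filter(study$censuses, census == 1, status == "alive")
  c2 <- dplyr::filter(study$censuses, census == 2)
  key <- function(d) paste(d$tree_id, d$stem_id)
  died_keys <- key(dplyr::filter(c2, status == "dead"))
  dying <- c1$dbh[key(c1) %in% died_keys]
  surviving <- c1$dbh[!(key(c1) %in% died_keys)]
  expect_gt(mean(dying), mean(surviving))
})

test_that("disturbance concentrated in the valley removes more biomass there", {
  losses <- sapply(1:5, function(s) {
    study <- simulate_study(sim_config(n_species = 40, mean_stems = 60,
                                       n_censuses = 2, seed = 100 + s,
                                       null = null_spec(n_iterations = 9, seed = s)))
    sp <- suppressWarnings(suppressMessages(impute_wood_density(study$species)))
    agb <- quadrat_agb(study$censuses, sp,
                       quadrats = study$landscape$quadrats$quadrat, quiet = TRUE)
    j <- dplyr::left_join(agb, study$landscape$quadrats, by = "quadrat") |>
      dplyr::group_by(habitat, census) |>
      dplyr::summarise(agb = mean(agb), .groups = "drop") |>
      tidyr::pivot_wider(names_from = census, values_from = agb)
    c(h1 = j$`1`[j$habitat == "H1"] - j$`2`[j$habitat == "H1"],
      h3 = j$`1`[j$habitat == "H3"] - j$`2`[j$habitat == "H3"])
  })
  expect_true(all(losses["h1", ] > losses["h3", ]))
})

test_that("a noise-free embedded effect is recovered to numerical precision", {
  cfg <- sim_config(n_species = 40, mean_stems = 60, n_censuses = 2,
                    embedded_effects = c(cMPD = 0.5), noise_sd = 0,
                    null = null_spec(n_iterations = 99, seed = 5), seed = 3)
  study <- simulate_study(cfg)
  tr <- study$truth$realized
  expect_lt(max(abs(tr$achieved_d_agb - tr$target_d_agb)), 1e-6)
  sp <- suppressWarnings(suppressMessages(impute_wood_density(study$species)))
  agb <- quadrat_agb(study$censuses, sp,
                     quadrats = study$landscape$quadrats$quadrat, quiet = TRUE)
  df <- dplyr::inner_join(delta_agb(agb), tr, by = c("quadrat", "interval"))
  fit <- stats::lm(d_agb ~ cMPD, data = df)
  expect_equal(unname(coef(fit)["cMPD"]), 0.5, tolerance = 1e-8)
  expect_lt(abs(unname(coef(fit)[1])), 1e-8)
})

test_that("embedded-effect names are validated against produced covariates", {
  cfg <- light_config(seed = 1, embedded_effects = c(notACovariate = 1))
  expect_error(simulate_study(cfg), "notACovariate")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(habitat_fractions = c(H1 = 0.5, H2 = 0.5, H3 = 0.5)),
               "sum to 1")
  expect_error(sim_config(n_censuses = 1), ">= 2")
  expect_error(sim_config(plot_cols = 1), "2 x 2")
  expect_error(sim_config(recruitment_rate = -1), ">= 0")
  expect_error(sim_config(n_species = 1), ">= 2")
})
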