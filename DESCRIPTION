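Package: agbdrivers
Title: Drivers of Aboveground Biomass Dynamics in Stem-Mapped Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for decomposing the drivers of aboveground
    biomass change in stem-mapped forest dynamics plots. Estimates stem- and
    quadrat-level aboveground biomass from diameter censuses via height and
    biomass allometry with genus/family wood-density imputation; computes four
    dimensions of quadrat-level diversity (taxonomic, structural, phylogenetic,
    functional) including null-model standardized effect sizes of mean pairwise
    and nearest-taxon distances, functional dispersion and Rao's quadratic
    entropy on Gower trait distances; derives topographic covariates from a
    corner-elevation grid; and regresses biomass change on scaled covariates
    per time interval and habitat stratum with variance-inflation filtering,
    exhaustive lowest-AIC subset selection, and hierarchical partitioning of
    relative importance. A seedable synthetic forest-census generator with
    embedded, recoverable covariate effects makes the whole pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
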