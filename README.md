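# agbdrivers

Drivers of aboveground-biomass dynamics in stem-mapped forest plots.

Large forest dynamics plots re-census every tagged woody stem (DBH ≥ 1 cm)
on a fixed grid of 20 m × 20 m quadrats every few years. A central question
in biodiversity–ecosystem-functioning research is which *abiotic* factors
(topography, habitat) and which *dimensions of biodiversity* — taxonomic,
structural, phylogenetic, functional — drive the change in aboveground
biomass (ΔAGB) between censuses, and how those drivers shift across time
intervals and habitat strata. `agbdrivers` implements that analysis
end-to-end, together with a fully seedable synthetic forest-census generator
so every stage can be tested — including recovery of effects whose size is
known by construction.

## The pipeline

**Biomass.** Tree height from species-specific power-law allometry
`H = a·D^b·CF` (pooled coefficients for species without their own fit), stem
biomass from the compound allometry

```
AGB = 0.0673 · (WD · D² · H)^0.976     [kg; D in cm, WD in g/cm³, H in m]
```

with missing wood density imputed from congener, then confamilial, then
pool-wide means. Quadrat AGB is the sum over alive stems (all stems of
multi-stemmed trees), converted to Mg ha⁻¹; ΔAGB is the later-minus-earlier
difference per quadrat and interval.

**Topography.** Per quadrat, from the surveyed corner-elevation grid:
elevation (corner mean), slope (mean of the four 3-corner planes), aspect
(downslope bearing of the least-squares plane), convexity (elevation minus
the 8-neighbour mean; edge quadrats: centre minus own-corner mean).

**Diversity.** Per quadrat and census, eleven indices across four
dimensions: Shannon `H`, Gini–Simpson `D`, Pielou `J`; stand density `SD`
and `CV_DBH = σ/μ`; null-model standardized effect sizes of mean pairwise
and nearest-taxon distance on phylogenetic cophenetic distances
(`MPD`, `MNTD`, `SES = (obs − null mean)/null sd`, taxa-shuffle null, 999
iterations) and, sign-flipped, on a UPGMA trait-dendrogram (`traitMPD`,
`traitMNTD`); functional dispersion `FDis` and Rao's quadratic entropy
`RaoQ` on the Gower trait matrix (wood density, maximum height, life form).
Change values (`cH`, `cMPD`, …) are interval differences.

**Drivers.** Per interval × stratum (whole plot, H1 low-valley, H2
mid-hillside, H3 high-ridge): Wilcoxon rank-sum comparisons of AGB between
censuses; then ΔAGB regressed on the z-scored covariates with iterative
VIF > 5 removal, exhaustive lowest-AIC subset selection (Gaussian GLM), and
Chevan–Sutherland hierarchical partitioning of R² into per-predictor and
per-dimension relative importance (%).

## Worked example

```r
library(agbdrivers)

study <- simulate_study(sim_config(seed = 1))   # 120 quadrats, 160 species, 3 censuses
pipeline <- run_pipeline(study)
pipeline
#> agb_pipeline: 3 censuses, 120 quadrats, 8 driver-model cells
#> # A tibble: 3 × 3
#>   census mean_agb sd_agb
#>    <int>    <dbl>  <dbl>
#> 1      1     200.  110. 
#> 2      2     181.   95.5
#> 3      3     183.   96.0
```

Mean quadrat biomass falls from ~200 to ~181 Mg ha⁻¹ in the first interval
(the generator's size-biased disturbance pulse, concentrated in the
low-valley habitat) and partially recovers afterwards. The driver models:

```r
glance(pipeline$drivers)        # one row per interval × stratum cell
tidy(pipeline$drivers$fits[["interval1_whole"]])   # coefficients + importance
autoplot(pipeline$drivers$fits[["interval1_whole"]])  # forest-style plot
plot_dimension_importance(pipeline$drivers)
```

A known effect can be embedded and recovered:

```r
cfg <- sim_config(n_species = 40, mean_stems = 60, n_censuses = 2,
                  embedded_effects = c(cMPD = 0.5), noise_sd = 0, seed = 3)
study <- simulate_study(cfg)
truth <- study$truth$realized
fit <- lm(d_agb ~ cMPD,
          data = merge(delta_agb(quadrat_agb(study$censuses,
                         impute_wood_density(study$species))), truth))
coef(fit)[["cMPD"]]
#> [1] 0.5
```

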