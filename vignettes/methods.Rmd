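---
title: "Methods: biomass dynamics, multidimensional diversity, and driver decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomass dynamics, multidimensional diversity, and driver decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`agbdrivers` analyses how topography and four dimensions of biodiversity
drive the change in aboveground biomass (ΔAGB) between censuses of a
stem-mapped forest plot. This vignette is the package's account of the
models it implements, the choices made where several defensible definitions
exist, and what the bundled synthetic study system does and does not
emulate.

## Biomass model

Stem biomass is a two-stage allometry. Height is predicted from diameter at
breast height by `H = a·D^b·CF`, where `a`, `b` are species-specific
log-log regression coefficients and `CF` is the back-transformation
correction factor of that regression; species without their own fit use a
pooled all-species set (default `a = 1.5`, `b = 0.6`, `CF = 1.02`, all
configurable), and the number of stems biomassed with pooled coefficients
is reported. Stem biomass is `AGB = 0.0673·(WD·D²·H)^0.976` with `D` in cm,
`WD` (wood density) in g cm⁻³ and `H` in m; we take the output unit as kg
per stem, the standard for this allometry family, and make the Mg ha⁻¹
conversion explicit (`/1000`, `×10000/area`). `CF` defaults to 1 when
absent. Every tagged stem of a multi-stemmed tree at or above the 1-cm
inclusion threshold is biomassed and summed, the ForestGEO convention;
stems with status other than alive contribute zero.

Missing wood density is imputed by the mean of congeners with observed
values in the same climate region, else confamilials, else the pool mean
(with a warning — that value carries no taxonomic signal); provenance is
kept per species. ΔAGB is the per-quadrat, later-minus-earlier difference
over each census pair, so changes telescope across consecutive intervals
by construction.

## Topographic variables

From the corner-elevation grid: quadrat elevation is the mean of its four
corners; slope is the mean angular slope of the four planes through each
triple of corners (the forest-dynamics-plot convention); aspect is the
compass bearing of steepest descent of the least-squares plane through the
corners, reported in degrees clockwise from north and undefined on a
perfectly flat quadrat. Convexity is quadrat elevation minus the mean of
its eight neighbours; for edge quadrats the definition — centre elevation
minus own-corner mean — evaluates to exactly zero here, because with only a
corner grid the centre must be interpolated bilinearly. We keep that
behaviour rather than substituting a partial-neighbour mean: it is the
stated convention, it makes a uniformly tilted plane have zero convexity
everywhere, and it leaves rotation/translation invariance intact. Aspect
enters the regressions untransformed by default (a circularity caveat worth
remembering); a northness transform is a one-line change in the model
frame if wanted.

## Diversity indices

Eleven quadrat-level indices in four dimensions, per census:

* **Taxonomic** — Shannon–Wiener `H = −Σ pᵢ ln pᵢ` (natural log), Simpson
  in the Gini–Simpson form `D = 1 − Σ pᵢ²` (so that, like `H`, larger is
  more diverse; the dominance form `Σ pᵢ²` is a switch), Pielou
  `J = H/ln S`, undefined for monocultures.
* **Structural** — stand density `SD` (stems ≥ 1 cm) and `CV_DBH = σ/μ`
  with the sample (n−1) standard deviation; undefined below two stems.
* **Phylogenetic** — standardized effect sizes of mean pairwise distance
  (MPD) and mean nearest-taxon distance (MNTD) on the phylogeny's
  cophenetic distances: `SES = (observed − null mean)/null sd`.
* **Functional** — the same SES metrics on the cophenetic distances of a
  UPGMA dendrogram of the Gower trait matrix, multiplied by −1 (the
  convention that makes larger values mean higher functional diversity);
  and functional dispersion (FDis) plus Rao's quadratic entropy
  (RaoQ = Σᵢⱼ pᵢpⱼdᵢⱼ) on the raw Gower matrix. The Gower dissimilarity
  weights wood density, maximum height (both range-scaled over the whole
  pool) and life form (simple matching) equally. FDis follows the
  Laliberté–Legendre construction: abundance-weighted distance to the
  abundance-weighted centroid in principal-coordinate space, truncating
  axes with non-positive eigenvalues.

**Null model.** The default scheme is the taxa shuffle — permuting species
labels on the distance matrix — which for presence-based metrics is
equivalent to drawing random species sets of the observed richness from
the pool; 999 iterations, seeded. Because the null then depends only on
richness, null moments are computed once per distinct richness value and
reused, which is what makes 999 iterations over hundreds of quadrats cheap.
A richness-and-occupancy-preserving independent-swap scheme is available by
configuration. Two numerical points deserve note. First, a Monte-Carlo null
sd converges to the *population* sd of the null distribution; an exact
enumeration oracle must therefore use the population (not n−1) sd over the
equally likely subsets for the two routes to agree, and the tests do so.
Second, degenerate cases are flagged missing rather than propagated:
richness below two (no pairwise distances) and null sd of zero (e.g. a
community containing the whole pool, where every shuffle is identical).
MPD and MNTD are presence-based by default, since the SES equations are
written over species; abundance weighting is a switch and follows the
picante convention (all individual pairs, including conspecific
zero-distance pairs).

Change values (`cH`, `cMPD`, …) are later-minus-earlier differences per
interval; missingness propagates.

## Driver analysis

AGB differences between censuses are first tested with two-sided Wilcoxon
rank-sum comparisons per stratum (exact p for small untied samples,
corrected normal approximation otherwise; a paired signed-rank variant is
exposed since quadrats are re-measured, but the unpaired test is the
default to match common practice).

For each interval × stratum cell the model frame holds ΔAGB as response
and 26 candidate predictors: 4 topographic variables, the 11 initial-census
indices, and their 11 change values. Quadrats with any missing cell are
removed listwise (counts reported); cells below 10 complete quadrats are
skipped with a warning. Response and predictors are z-scored, so
coefficients are standardized effects. Collinearity is handled by
iteratively removing the single predictor with the highest variance
inflation factor until all VIF ≤ 5; perfect collinearity (infinite VIF)
goes first. Model selection fits a Gaussian-identity GLM (ordinary least
squares) for every non-empty predictor subset and keeps the lowest
`AIC = n·ln(RSS/n) + 2(k+2)` (intercept and error variance counted; this
differs from `stats::AIC` only by the constant `n(ln 2π + 1)`, so the
selected model is identical). Ties break toward fewer predictors, then
lexicographic order; subset size is capped at `n − 3` so the error variance
stays estimable, and at 12 so the subsequent partitioning stays tractable.
Above 15 surviving predictors the search falls back to bidirectional
stepwise AIC with a message. The RSS is floored at `TSS·10⁻¹²` so an exact
fit cannot be "improved" by junk predictors through rounding noise.

Relative importance uses Chevan–Sutherland hierarchical partitioning with
R² as goodness of fit: the independent contribution of predictor *j* is
the average over hierarchy levels of the mean R² increment from adding *j*
to every subset without it; contributions sum exactly to the full-model R²
(an identity the tests verify against an all-orderings oracle), and joint
contributions — which may be negative — are reported as diagnostics.
Per-predictor importances are expressed as percentages of their sum and
grouped into the five dimensions (topographic, taxonomic, structural,
phylogenetic, functional), initial and change values mapping to the same
dimension. Importances are computed over the AIC-best model's predictors
only; predictors eliminated by VIF or not selected carry zero importance
in that cell's summary, which is worth remembering when comparing cells.

GLM family is Gaussian with identity link: the response is a real-valued
difference with both signs, and nothing in a 120-quadrat frame justifies a
heavier-tailed likelihood. No multiple-testing correction is applied
across cells; significance stars (0.05/0.01/0.001) are descriptive.

## The synthetic study system

The generator exists so that every stage — including the driver models —
can be exercised against known truth. Its defaults are fixed once to
emulate a 5-ha subtropical evergreen broad-leaved plot: a 10 × 12 grid of
20-m quadrats (120 analysed quadrats), 160 species, three censuses five
years apart, ~147 stems per quadrat (negative binomial, size 12), and a
V-shaped valley landscape (hillsides north and south, mild eastward tilt,
smoothed Gaussian noise) cut by elevation rank into exactly 50/45/25
quadrats of low-valley/mid-hillside/high-ridge habitat. Initial diameters
are 1 cm plus a gamma tail (shape 0.37, scale 16, capped at 1 m), which
puts initial plot biomass near 200 Mg ha⁻¹ — the magnitude reported for
mature subtropical plots. Species carry lognormal wood density (median
0.55 g cm⁻³) with nested family/genus effects so taxonomic imputation is
meaningful, 14.9% of wood densities withheld to exercise it, lognormal
maximum height, a three-level life form, a species-specific height fit for
roughly 29% of species, Dirichlet habitat-affinity weights (compositional
turnover across strata), and a unit-depth constant-rate birth–death
phylogeny. Dynamics per interval: truncated-normal diameter growth
(0.15 cm yr⁻¹, never negative), baseline mortality 0.05, recruitment of
~18 stems quadrat⁻¹ at 1.4–2.4 cm, and — in the first interval — an extra
mortality term proportional to `(D/10)^0.8`, weighted 1/0.4/0.15 across
H1/H2/H3: a size-biased disturbance pulse concentrated in the valley, the
signature of an ice-storm event. The published per-interval demographic
rates for such plots are not tabulated anywhere we could source, so these
are plausibility choices, fixed once; they produce a decline of roughly
10% in mean AGB followed by partial recovery, concentrated in H1.

**Embedded effects.** With `embedded_effects = c(cMPD = 0.5)` (say), each
interval's quadrat ΔAGB is rewritten as `Σ βₖ·z(xₖ) + ε`,
`ε ~ N(0, noise_sd)`, where `xₖ` are the *realized* covariates of the
simulated study. The adjustment is carried by a uniform within-quadrat
rescaling of the later census's diameters (a root-find per quadrat, with a
1-cm floor): because biomass is recomputed from diameters downstream, an
adjustment stored anywhere else would be invisible to the very analysis it
is meant to drive, and a *uniform* diameter rescaling moves quadrat biomass
while leaving every diversity covariate untouched — counts, composition,
SES metrics, FDis/RaoQ do not involve diameter, and CV_DBH is
scale-invariant. Quadrats whose covariate is undefined (e.g. monodominant,
so cMPD does not exist) are left unadjusted with a warning, and quadrats
whose target would fall below the biomass of all stems at the 1-cm floor
record their achieved value in the truth table. With `noise_sd = 0`,
regressing ΔAGB on the realized covariate returns the embedded coefficient
to numerical precision — the package's sharpest end-to-end test.

**What the generator does not emulate:** spatially explicit stem mapping
within quadrats, neighbourhood competition, seed dispersal, climate
forcing, measurement error in DBH, and spatial autocorrelation of
composition beyond what habitat affinity induces. Passing tests therefore
demonstrate correctness of the estimators and the recovery machinery, not
that real forests satisfy the models' assumptions.

## Problem sizes and determinism

The test suite runs reduced configurations chosen as the smallest that
still exercise each property: 20–30-quadrat studies for round-trip and
bookkeeping tests; the full 120-quadrat, two-census design with 40 species,
~30 stems per quadrat and 99 null iterations for the 200-replicate
effect-recovery experiment (the embedded +0.5 effect with unit noise is
recovered, selected and positive, in well over 90% of replicates); a
6-species pool against exhaustive enumeration for the SES oracle; and 500
null-drawn communities for SES calibration (|mean| ≤ 0.1, sd within
0.85–1.15). Every stochastic component — generator, null models, test
fixtures — is seeded; a study is a pure function of its configuration, and
rerunning the pipeline writes byte-identical files (no timestamps in
outputs; the seed is recorded in every CSV header and in the JSON
summaries).

## Known limitations

Aspect is treated as linear degrees; the SES null models assume the species
pool is the plot's own census; hierarchical partitioning is limited to 12
selected predictors; the stepwise fallback above 15 candidates does not
guarantee the AIC optimum; and relative-importance percentages are
conditional on the selected model, so cells with different selected subsets
are not strictly comparable predictor-by-predictor. Edge-quadrat convexity
is identically zero by construction, which slightly attenuates convexity
effects estimated over strata containing many edge quadrats.
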