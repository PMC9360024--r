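---
title: "Methods: population-weighted greenspace exposure, inequality, and drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-weighted greenspace exposure, inequality, and drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenexposure)
```

## The exposure model

The package assesses human exposure to greenspace on a common 100 m-class
lattice carrying two variables: the fractional greenspace coverage
$G_i \in [0,1]$ of each cell (obtained by `aggregate_fraction()` from a
finer binary greenspace/not map, e.g. 10 m classified land cover
aggregated by a factor of 10) and the resident population count
$P_i \ge 0$ of each cell.

Two zonal statistics summarize a zone of $N$ valid cells:

* physical coverage $GC = \sum_i G_i / N$ — how green the zone is,
  regardless of where anyone lives; and
* population-weighted exposure
  $GE^d = \sum_i P_i G_i^d \,/\, \sum_i P_i$, where
  $G_i^d$ (`focal_fraction()`) is the mean greenspace fraction over all
  cells whose **center** lies within Euclidean distance $d$ of cell $i$'s
  center — the greenness of a resident's nearby environment.

The gap between the two is the point of the method: wherever population
concentrates away from greenspace, $GE^d < GC$ and coverage statistics
overstate the exposure people actually receive; where people cluster in
green surroundings the inequality runs the other way.

### Discretizing the buffer

The circular buffer is discretized on cell centers with an *inclusive*
boundary ($\le d$), so at $d$ equal to one cell size the kernel is the
center plus its four orthogonal neighbours, and any $d$ smaller than the
cell size reduces `focal_fraction()` to the identity. This convention is
symmetric, deterministic, and testable by direct enumeration (the test
suite compares against a brute-force double loop at $10^{-10}$).

At grid edges and around nodata cells the kernel is renormalized over the
cells actually available. The alternative — zero-padding — would
systematically depress exposure at city fringes for no physical reason.
For the same reason the buffered fraction is computed over the **full**
raster before zonal masking: greenspace just outside an administrative
boundary is still part of a resident's nearby environment.

Cells with $P_i = 0$ contribute nothing to $GE^d$ but still count in
$GC$; a zone with zero total population has undefined exposure and is
flagged rather than silently zeroed. All fractions are carried in $[0,1]$
internally; percentages appear only in reporting.

## Inequality: the population-weighted Gini

Within a zone, exposure inequality is the population-weighted Gini index
of the per-cell pairs $(G_i^d, P_i)$ at the primary radius. Cells are
sorted by exposure (ties kept in cell order — the index is tie-order
invariant, so this only affects the stored curve), the Lorenz curve of
cumulative population share versus cumulative exposure share is built at
cell resolution, and

$$\mathrm{Gini} = 1 - 2 \int_0^1 L(x)\,dx$$

with the integral taken by the trapezoidal rule over the cell-level
points. No binning or percentile grouping is applied: at cell resolution
the trapezoidal value agrees with the $O(n^2)$ pairwise-difference
definition to $10^{-10}$, which the suite verifies on a thousand random
instances, along with scale invariance, population-replication invariance
and the transfer principle.

A zone whose weighted exposure is identically zero has an undefined Lorenz
share; it is reported as Gini 0 with a `degenerate` flag (and excluded
from driver analysis) instead of erroring, so batch runs over thousands of
zones complete. Inequality categories use half-open intervals with
configurable thresholds, defaulting to 0.3 and 0.5 — chosen to bracket the
regional mean Ginis (roughly 0.2–0.27 for well-provisioned regions versus
0.41–0.47 for poorly provisioned ones) so that "medium" spans the
transition; the original analysis never published its cut-offs.

## Seasonal statistics

Exposure is seasonal because deciduous vegetation loses greenness in
winter. Given four seasonal greenspace grids, `seasonal_report()` computes
per-season $GE^d$, Gini, and the coefficient of spatial variation
$csv = \sigma/\mu$ of the gridded exposure within the zone, then
$cstv = \mathrm{std}(\{csv_1..csv_4\})$ and the summer-minus-winter Gini
difference.

Two conventions had to be fixed:

* **Population SD.** $\sigma$ and the std in $cstv$ use the population
  (divide-by-$n$) convention: the four seasons are the complete set of
  seasons, not a sample. The choice is configurable
  (`gx_config(sd_convention=)`) and only rescales both statistics by a
  common factor.
* **csv is spatial, not population-weighted.** $csv$ is computed over the
  per-cell exposure field $G^d$ within the zone, because it measures the
  spatial variability of the exposure surface; the weighting enters
  through the Gini, not through $csv$.

Season labels depend on hemisphere (December–February is summer in the
south), so every zone must declare `"N"` or `"S"`; zones straddling the
equator must pick one or are flagged. A stack keyed by calendar quarters
(`DJF/MAM/JJA/SON`) is mapped to seasons per zone; a stack already keyed
by season names is used as-is.

The property test relating seasonal change of inequality to seasonal
variation regresses $|Gini_{summer} - Gini_{winter}|$ on $cstv$ across a
synthetic collection; both the $cstv$ regression and the
summer-minus-winter $csv$ difference (`dcsv_sw`) are emitted so either
reading of the seasonal-attribution relation can be reproduced.

## Landscape metrics

The driver analysis needs configuration covariates from a binary
greenspace map: patch count and sizes, perimeter–area ratio, shape index
$0.25 P/\sqrt{A}$ (1 for a solid square), and edge density (total patch
perimeter per zone area, m/ha). Decisions:

* connected components default to 8-connectivity (the common
  landscape-ecology choice; 4 is available),
* perimeters always use the 4-neighbourhood, and an edge against nodata or
  the raster boundary counts as exposed — this keeps per-patch perimeter
  sums exactly equal to a brute-force edge scan, which the suite asserts,
  at the cost of inflating the perimeter of clipped patches (the opposite
  convention exists; this one is recorded in the output header),
* "largest patch size" is emitted both as absolute area (m²) and as the
  largest-patch index (fraction of zone area), since both usages occur,
* fractional maps are binarized at 0.5 by default before patch analysis.

## Driver attribution

Sixteen city-level covariates in five categories (geographic lat/lon,
topographic elevation/slope, climate prcp/temp/vpd, socioeconomic
ntl/pop_density/road_length, landscape gcr/patch statistics/ed) are
min–max rescaled to $[0,1]$ (`rescale_01()`; the Gini response stays
raw — constant columns are flagged and excluded). Screening keeps
covariates passing all of: Pearson $p < 0.001$, $|r| > 0.1$, and partial
correlation $|r_p| > 0.1$ controlling all other covariates. The partial
correlation is computed from the precision matrix; the tests verify it
against the independent residual-regression route. P-values are two-sided
and uncorrected — the procedure applies fixed thresholds rather than an
FDR-controlled selection, and this is documented rather than "fixed".

`ols_nested()` fits the model ladder (geography; climate; landscape; all
five screened covariates). Coefficients are reported **both** on the
rescaled-covariate/raw-response scale and as fully standardized
coefficients, because published regression tables are ambiguous between
the two conventions; with rescaled predictors the intercept sits near the
response mean. `vif()` computes $1/(1-R_j^2)$ per covariate from
per-column regressions (cross-checked against `car::vif`), with an `Inf`
flag for perfect collinearity.

`variance_partition()` splits the explained variance of the Gini between
greenspace provision (`gcr`) and configuration (`ed`) using the adjusted
$R^2$ of the three fits A, B, A∪B — the commonality-analysis convention of
`vegan::varpart`, against which the tests cross-check; raw $R^2$ is
available by argument. The four fractions sum to 1 algebraically; a
negative joint fraction (suppression) is reported as-is with a warning.

## Synthetic data: what it emulates and what it does not

The generators provide ground truth for testing, emulating the
statistical structure of the real inputs:

* `gen_gaussian_field()` — FFT spectral filtering of white noise with a
  Gaussian correlogram of scale `correlation_length`; sample-standardized;
  seed-deterministic.
* `gen_greenspace()` — rank-transforms the field to $[0,1]$ and solves a
  monotone power adjustment (`uniroot` on the exponent) so the grid mean
  equals `target_coverage` to within $1/(2\,n_{cells})$. The default
  coverage 0.35 and the 100 m cell size match the scale of the original
  gridded analysis; correlation length defaults to 500–800 m, the scale of
  parks and districts rather than individual trees.
* `gen_population()` — lognormal intensity whose log mixes the
  standardized greenspace field (weight `pop_green_corr`) with an
  independent field, scaled to `pop_total` and integerized by largest
  remainder so totals are **exactly** conserved. `pop_green_corr` is a
  free knob, not an estimate: the joint population–greenspace distribution
  of real cities is not characterized by a single number. The pipeline's
  default of −0.3 encodes the empirically ubiquitous pattern of people
  concentrating in less green cells, which is what produces the
  coverage-overestimates-exposure signature.
* `gen_seasonal_stack()` — summer is the base state; a seeded per-cell
  draw marks a `deciduous_fraction` of green cells, scaled by
  `winter_retention` in winter and `shoulder_retention` in spring/autumn.
  Evergreen cells are constant. This reproduces phenology's first-order
  effect (amplitude heterogeneity across cities) but not spatial
  contiguity of deciduous stands or gradual green-up.
* `gen_city_collection()` — independent truncated-normal covariates with
  field-realistic means/sds, response = planted linear combination of the
  rescaled covariates + Gaussian noise, clipped to $[0,1]$ (clip counts
  are returned; recovery tests run in regimes where clipping is absent).
  Default planted coefficients are a landscape-only model (intercept
  0.355, gcr −0.115, ed −0.047) with noise sd 0.05, i.e. moderate effects
  at the scale of published city-level inequality regressions.

Passing tests on these data show the *estimators* are correct and the
qualitative mechanisms (overestimation, seasonal inequality swings,
provision/configuration attribution) emerge as designed. They do not show
that real cities satisfy the generators' assumptions — real landscapes
have road networks, districts, demographic strata and anisotropic
phenology none of which are modelled.

## Numerical and interface choices

* **Raster format.** Grids are read and written as ESRI ASCII rasters
  (plain text, lossless at float32 printing precision) with a `.prj` WKT
  sidecar. A raster without a CRS is rejected as unreferenced, and a
  geographic (degree) CRS is rejected with an instruction to reproject:
  buffer distances are in metres, so a projected metric CRS is a
  precondition, and the projection choice is left to the user. All grids
  in one analysis must share cell size and alignment; resampling is out
  of scope and a mismatch is an error, never silent interpolation.
* **Rasterization** assigns each cell to the zone containing its center
  (boundary inclusive, "covers" semantics); overlapping zones resolve to
  the first zone in list order with a warning.
* **Aggregation** requires exact divisibility of dimensions — no implicit
  padding — and a coarse cell is nodata only when its whole block is.
* **Interface.** The exported functions are the interface; the scripted
  end-to-end path is `run_pipeline()`, which the acceptance script
  drives, and a flat YAML config (`read_config()`) carries the tunable
  thresholds. Runs write a JSON manifest of all parameters, seeds and
  versions next to their outputs.
* **Problem sizes.** The shipped experiments use a 256 × 256-cell scene
  (100 m cells, ~658 km²) with 100 pseudo-cities, 48 × 48-cell cities for
  the 100-city seasonal collection, and 1000-city driver tables — large
  enough for stable statistics while keeping a full pipeline run in
  seconds.

## Known limitations

* Exposure is residence-based; daily mobility is not modelled.
* No demographic stratification of population, and no distinction between
  greenspace types (tree versus shrub/grass) in exposure.
* The Gini is not decomposable by subgroup; decomposable indices (Theil,
  Atkinson) are out of scope.
* Screening p-values are uncorrected for the 16 tests, matching the
  fixed-threshold procedure it implements.
* The rasterizer handles simple polygons without holes — adequate for the
  rectangular pseudo-cities and simple administrative stand-ins it is
  meant for.
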