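---
title: "Methods: multi-criteria mapping of salt-dust health risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria mapping of salt-dust health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltrisk)
```

## Overview

`saltrisk` maps the vulnerability of a population to wind-borne salt dust
from a shrinking hyper-saline lake. The pipeline has five stages:
standardize heterogeneous criterion rasters to fuzzy [0, 1] memberships;
derive criterion importances from expert pairwise comparisons; aggregate
pixel-wise with a quantifier-guided ordered weighted average (OWA);
quantify how weight uncertainty propagates into the map; and relate the
map to health outcomes (prevalence panels, density hotspots, spatial
autocorrelation, trend association). This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions that
were genuinely open.

## Data model and raster conventions

A `grid_layer` is a numeric matrix with an upper-left origin in projected
meters and a square cell size; `NA` is nodata. Cell `[1, 1]` is the
north-west corner and all point arithmetic uses cell centers. The package
performs no reprojection: a free-text CRS tag is carried as opaque
metadata and compared for equality where layers meet, which keeps the
numerics fully testable. Rasters are exchanged as ESRI ASCII grids, a
plain-text georeferenced single-band format whose header carries the
geotransform; values are printed with 17 significant digits so IO
round-trips are exact.

When layers arrive on different grids, `align()` resamples them onto a
common target: bilinearly for continuous fields, nearest-neighbor for
classed ones (declared per layer, so class rasters can never acquire
interpolated pseudo-classes). Nodata propagates — a target cell whose
support touches a masked source cell is masked, never silently zeroed.
The resampling rule is this package's contract; no claim is made that it
matches how any particular study harmonized its sources.

## Fuzzy standardization

Each criterion is mapped to a membership `m ∈ [0, 1]` that reads as
"contribution to risk". Continuous criteria use a linear ramp between two
anchors `lo < hi` in native units, with *benefit* direction
(`m = (v − lo)/(hi − lo)`; higher raw value, higher risk — e.g. wind
speed) or *cost* direction (`m = (hi − v)/(hi − lo)`; e.g. distance to a
salt source, where proximity is the hazard). Values outside the ramp are
clamped rather than rejected, so the operation is total on extreme
synthetic inputs. Classed criteria use an explicit class → membership
table, which already encodes direction; an unmapped class is a hard
error naming the class. Nonlinear (sigmoidal) memberships are not
offered; the linear ramp plus a free classed table covers the analyses
the package targets.

The default specification set (`default_criterion_specs()`) covers the
eleven canonical criteria. The distance-to-salt-center ramp spans 0–80 km
(cost): beyond 80 km exposure membership is zero. Membership values for
classed criteria (e.g. age bands rising from 0.15 for the youngest to
1.0 for the oldest band) are package defaults chosen to express the
qualitative ordering of vulnerability; they are fully config-driven and
meant to be replaced by study-specific tables.

## Expert weighting

Importance weights derive from reciprocal pairwise-comparison matrices on
the 1–9 scale. Several experts' matrices are combined by the element-wise
geometric mean — the only aggregation that preserves reciprocity by
construction — and weights are the normalized principal right
eigenvector, computed by power iteration to a relative tolerance of
1e-10. Consistency is scored by `CR = ((λ_max − n)/(n − 1))/RI(n)` with
Saaty's random-index table (n ≤ 15); CR below 0.1 is the conventional
acceptance bar, and a perfectly transitive matrix scores exactly 0.

The "fuzzy analytic network process" label that often attaches to such
weight sets is implemented here as crisp single-cluster eigenvector
weighting: with no published supermatrix, cluster structure, or
fuzzification detail to reproduce, this is the minimal faithful reading,
and the packaged reference weight table (`fanp_reference_weights()`)
lets users bypass the weighting stage entirely. The printed reference
weights sum to ≈ 0.9898 and are renormalized to sum exactly 1 on load so
they satisfy the weight-vector contract.

## Ordered weighted averaging

At each cell the memberships are sorted descending, z₍₁₎ ≥ … ≥ z₍ₙ₎, each
carrying its criterion's importance u along with it. With the
regular-increasing-monotone quantifier Q(p) = pˣ, the order weight of
sort position j is

  Vⱼ = (Uⱼ/Uₙ)ˣ − (Uⱼ₋₁/Uₙ)ˣ,  Uⱼ = Σ_{I ≤ j} u_I,

and the cell value is Σⱼ Vⱼ z₍ⱼ₎. The Vⱼ telescope to exactly 1, the
result is a convex combination of memberships (so bounded by their min
and max), and the operator is monotone both in every membership and,
non-increasingly, in x. At x = 1 it reduces to the plain
importance-weighted mean (weighted linear combination); x < 1 shifts
mass toward the largest memberships (optimistic / OR-like,
risk-amplifying), x > 1 toward the smallest (conservative / AND-like).
The package fixes the *descending* sort convention — common in the OWA
literature, where prose descriptions sometimes say "ascending" while the
formula sorts descending — and documents the x ↔ behavior mapping above.
The default is x = 1 (neutral), since no particular decision attitude is
canonical. Ties in the sort break by the stable criterion declaration
order, so results are bit-reproducible across platforms. A zero weight
is permitted: such a criterion contributes zero-width quantifier
increments and is effectively ignored.

Classification (`classify_risk()`) cuts the aggregated surface into
ordered classes either at fixed equal intervals k/n (the default, so
class boundaries are interpretable absolutely) or at empirical type-7
quantiles of the unmasked cells (equal-area classes); a near-constant
surface makes quantile breaks degenerate and raises an error that
suggests equal intervals.

## Weight-uncertainty analysis

Weights are the soft spot of any multi-criteria analysis, so the package
quantifies their influence three complementary ways. All are driven by
independent uniform relative perturbation: each sampled weight is drawn
from `U(w(1 − p), w(1 + p))` around its reference, with `p = 0.2` by
default (a ±20 % band is a conventional stress level for expert-derived
weights; the published definitions leave the sampling law unstated).
Draws are kept raw for the instability statistic and renormalized to sum
1 inside any model that consumes them; that renormalization induces mild
negative correlation between factors, a documented departure from the
independence assumed by the variance decomposition.

1. **Instability statistic.** `T = √(mean((δᵢ/wᵢ)²))` with δ the raw
   deviation of a sampled weight from its reference, averaged over all
   draws and criteria. The deviation δ is not defined in the published
   statistic; defining it as sampled-minus-reference makes T a
   dimensionless coefficient with exact anchors — 0 when nothing is
   perturbed, 1 when every weight doubles — and the analytic value
   p/√3 ≈ 0.1155 under ±20 % uniform noise.
2. **Rank shifts.** The average shift in ranks,
   `ASR = (1/n) Σ |rank_ref − rank|`, is computed per draw both for
   criteria (options = criteria ranked by weight) and for locations
   (options = sampled cells ranked by risk). Per-location rank
   min/max/mean/sd across runs are completed to full surfaces by
   inverse-distance interpolation, mirroring how rank-stability maps are
   produced from sampled training locations.
3. **Sobol indices.** First-order and total-effect indices of the risk
   output with respect to each weight factor, estimated with the
   paired-matrix Saltelli design: `Sᵢ = mean(f_B (f_{ABᵢ} − f_A))/V` and
   Jansen's `STᵢ = mean((f_A − f_{ABᵢ})²)/(2V)`. These estimators are the
   standard recommendation for this design; the published index
   *definitions* alone do not pin an estimator down. Estimates are
   returned raw (values marginally outside [0, 1] are estimator noise).
   The default base sample is 1024 (total evaluations 1024·(k + 2));
   the model evaluated is the mean OWA risk over a random subset of
   cells, the natural scalar summary when the output is a whole map.

## Health-outcome analytics

- `build_panel()` tabulates hypertensive cases per year and sex against a
  fixed cohort denominator and reports prevalence exactly (two printed
  decimals); no attempt is made to reproduce externally rounded
  percentages, which can differ from exact arithmetic by ≤ 0.01.
- `kde_surface()` smooths case locations with an isotropic Gaussian
  kernel, evaluated exactly via the separable row/column factorization,
  so the surface integrates to the case count up to edge loss. The
  default bandwidth is Silverman's rule averaged over the axes —
  standard, and overridable.
- `morans_i()` computes global Moran's I over row-standardized queen
  (default) or rook contiguity among unmasked cells — the most common
  defaults where no weights matrix is published — with a permutation
  test, two-sided on the distance from the null expectation −1/(n − 1).
  Only the global index is offered: local indicators (local Moran, Gi*)
  are a different inferential tool and deliberately out of scope.
- `correlate_layers()` reports the Pearson correlation between an
  outcome surface and a criterion over shared unmasked cells, plus the
  criterion-binned mean outcome used for correlation plots.
- `trend_association()` correlates an annual driver series with annual
  prevalence over shared years (Pearson or Spearman via `cor.test`).

## The synthetic scenario

Because survey health records of this kind are access-restricted, the
package ships a generator whose output has the statistical structure the
analysis assumes, so every stage is testable without external data. The
default configuration is the study scale the package is designed around:
a 200 × 200 grid of 20 m cells (a 4 × 4 km desk-scale region, not a full
county — runtime is the only reason), three salt-emission centers, a
fixed cohort of 12,000 adults aged 15–64 followed over 2012–2020, and an
annual driver series (exposed salt-land area, km²) that rises and then
falls across the panel.

Exposure at distance d from the nearest source is
`exp(−d/λ) · amp`, with decay length λ = 1500 m and amp = 1.5 inside the
±45° downwind cone (1 elsewhere). The exposure formula is this package's
construction — the causal direction (proximity and downwind position
increase risk) is the assumption being emulated, but no residence-level
exposure model is published — so λ and the cone are explicit
configuration, intended to be varied in sensitivity exercises rather
than read as estimates. Individual outcomes are Bernoulli draws from
`logit p = β₀ + β₁ s_y E + β₂ (age − 40) + β₃ female`, where `s_y`
scales the exposure effect proportionally to the annual driver. The
defaults β₀ = logit(0.012), β₁ = 4.2, β₂ = 0.035 / yr, β₃ = 0.25 were
calibrated once so the panel spans roughly 2 % prevalence in the first
year to ≈ 18 % at peak — the magnitude such surveys report — and so that
females show a modest excess. Because the exposure effect is tied
proportionally to the driver, the synthetic prevalence peaks with the
driver (2017) rather than later; the generator makes no attempt to model
lagged or saturating dose response.

What passing tests on this scenario do show: the pipeline recovers a
planted exposure gradient (risk–exposure correlation, near-source
prevalence excess), the logistic coefficients are recoverable by a GLM
refit, and every stage is deterministic given the seed. What they do not
show: performance on real county-scale geodata, realistic meteorology or
land-cover spectra, spatial confounding between population structure and
exposure, or any lagged dose–response — the generator draws demographic
fields independently of exposure by construction.

## Numerical choices and degenerate inputs

- Power iteration stops at relative 1e-10; non-convergence (pathological
  inputs only) is an error, never a silent result.
- OWA order weights telescope to 1 exactly; the aggregation validates
  [0, 1] membership ranges and grid alignment before computing.
- IDW uses power 2 and 12 neighbors by default (the method's customary
  parameters; none are canonical); a cell coinciding with a sample takes
  the sample's value exactly, and the distance matrix is processed in
  chunks to bound memory.
- Degenerate inputs fail loudly with the stage named: constant surfaces
  under quantile classification, zero-variance attributes in Moran's I
  and correlations, constant driver series, empty sample sets,
  single-run rank stability.
- Reported prevalence is exact; printing rounds to 2 decimals.

## Problem sizes

The shipped tests exercise the full pipeline at the default 200 × 200 /
12,000-cohort scale for the end-to-end recovery checks, with 10,000
Monte-Carlo weight draws for the instability statistic, Sobol base
samples of 4096 for the closed-form benchmark, and smaller grids for the
oracle-vs-implementation equivalence suites (where brute-force oracles
are quadratic). These sizes were chosen as the package's reference
conditions; all are configuration, not limits.

## Known limitations

- No reprojection, multi-band imagery, or remote-sensing preprocessing;
  inputs must arrive on a shared CRS.
- The weighting stage is single-cluster (no inter-criterion dependence
  network); a full supermatrix ANP is out of scope.
- The linear quantifier family Q(p) = pˣ is the only one offered.
- Associations reported by the health analytics are descriptive; the
  package makes no causal claims, and no age-standardization of rates is
  performed.
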