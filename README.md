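# saltrisk

Spatial multi-criteria mapping of population health risk from wind-borne
salt dust.

## The problem

When a hyper-saline lake shrinks, the exposed lakebed becomes a source of
wind-borne saline particulate ("salt-dust scatter"). Populations living
downwind of the exposed salt flats face elevated cardiovascular risk, and
public-health agencies need maps that say *where* that risk concentrates —
combining environmental drivers (distance to salt sources, wind direction
and speed, soil moisture, vegetation, terrain) with demographic
vulnerability (age structure, population density, existing hypertension).
`saltrisk` implements that analysis as a reusable R pipeline for
epidemiologists and spatial analysts, together with the uncertainty and
health-outcome statistics needed to defend such a map.

## What the package computes

- **Fuzzy standardization.** Each raw criterion raster is mapped to a
  membership m ∈ [0, 1] with benefit (`m = (v − lo)/(hi − lo)`) or cost
  (`m = (hi − v)/(hi − lo)`) semantics, clamped to [0, 1]; classed layers
  use explicit class → membership tables (`fuzzify()`).
- **Expert weighting.** Criterion importances w come from reciprocal 1–9
  pairwise-comparison matrices: element-wise geometric-mean aggregation
  over experts (`aggregate_experts()`), principal-eigenvector weights
  (`eigen_weights()`), and Saaty's consistency ratio
  (`consistency_ratio()`). A packaged reference table of expert-derived
  weights for the eleven canonical criteria ships with the package
  (`fanp_reference_weights()`).
- **Ordered weighted averaging.** At each cell the sorted memberships
  z₍₁₎ ≥ … ≥ z₍ₙ₎ are combined as OWA = Σⱼ Vⱼ z₍ⱼ₎ with
  quantifier-guided order weights Vⱼ = (Uⱼ/Uₙ)ˣ − (Uⱼ₋₁/Uₙ)ˣ, where Uⱼ
  accumulates the importances in sort order and Q(p) = pˣ. `x = 1`
  reproduces the weighted linear combination; `x < 1` is optimistic
  (OR-like), `x > 1` conservative (AND-like). (`owa_aggregate()`,
  `classify_risk()`.)
- **Weight-uncertainty analysis.** Uniform ±p perturbation of the weights
  with the instability statistic T = √(mean((δᵢ/wᵢ)²)), the average shift
  in ranks ASR = (1/n) Σ |rank_ref − rank|, per-location rank-stability
  surfaces (min/max/mean/sd of rank across runs, completed by IDW), and
  variance-based Sobol indices Sᵢ and STᵢ of the risk output
  (`weight_uncertainty()`, `sobol_indices()`, `mcs_instability()`,
  `average_shift_in_ranks()`).
- **Health-outcome analytics.** Sex-stratified prevalence panels
  (`build_panel()`), Gaussian kernel-density hotspot surfaces
  (`kde_surface()`), global Moran's I with permutation inference
  (`morans_i()`), criterion–outcome spatial correlation
  (`correlate_layers()`), and driver–prevalence trend association
  (`trend_association()`).
- **Synthetic scenario generator.** The survey data such analyses rest on
  are typically restricted, so `generate_scenario()` builds a fully
  synthetic study region — 11 criterion rasters on a common 20 m grid,
  salt sources with distance-decayed, downwind-amplified exposure, and a
  12,000-adult cohort whose hypertension follows a logistic model in
  exposure, age and sex — so the entire pipeline is testable end to end.

Rasters are exchanged as ESRI ASCII grids (`read_asc()` / `write_asc()`),
a plain-text single-band georeferenced format.

## Worked example

```r
library(saltrisk)

scn <- generate_scenario(scenario_config(seed = 7))
res <- run_pipeline(scenario = scn, sens_runs = 2000,
                    sobol_n_base = 128, moran_perm = 99, seed = 7)
res
#> <salt_pipeline>
#>   OWA exponent x = 1, 11 criteria
#>   risk surface: mean 0.479 (range 0.321-0.938)
#>   weight instability T = 0.115, mean criterion ASR = 0.209
#>   Moran's I of risk surface = 0.973 (p = 0.01)
#>   risk vs true exposure r = 0.755
#>   driver-prevalence trend r = 0.981 (p = 3.32e-06)

res$risk_map
#> <risk_map> 5 classes (equal-interval breaks)
#>   breaks: 0.2, 0.4, 0.6, 0.8
#>   very-low         0 cells (  0.0%)
#>   low           5171 cells ( 12.9%)
#>   moderate     30049 cells ( 75.1%)
#>   high          4531 cells ( 11.3%)
#>   very-high      249 cells (  0.6%)
```

Reading the output: the aggregated risk surface is strongly spatially
clustered (Moran's I ≈ 0.97, permutation p = 0.01), and it recovers the
exposure field the generator planted (r ≈ 0.76) even though exposure
enters only indirectly through the criterion layers. The instability
statistic T ≈ 0.115 matches the analytic value 0.2/√3 for ±20 % uniform
weight noise, and a mean ASR of ≈ 0.21 says that this perturbation
typically displaces a criterion by a fifth of a rank position — the
weighting is stable. The synthetic prevalence panel tracks the
salt-land driver (trend r ≈ 0.98).

The packaged observed panel behaves the same way:

```r
pan <- salt_panel()
pan[pan$year == 2019, c("year", "total", "prevalence_pct")]
#>  year total prevalence_pct
#>  2019  2340           19.5
trend_association(data.frame(year = pan$year, value = pan$salt_land_km2),
                  pan)$estimate
#>       cor
#> 0.5603338
```

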