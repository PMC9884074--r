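Package: saltrisk
Title: Spatial Multi-Criteria Health-Risk Mapping for Salt-Dust Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping population vulnerability and health risk from
    wind-borne salt dust around shrinking hyper-saline lakes. Standardizes
    heterogeneous environmental and demographic criterion rasters to fuzzy
    [0,1] memberships, derives criterion weights from expert pairwise
    comparison matrices (AHP-style eigenvector weighting with consistency
    checking), aggregates the standardized layers with a quantifier-guided
    Ordered Weighted Average into a classified risk surface, and quantifies
    weight uncertainty by Monte-Carlo perturbation, variance-based (Sobol)
    sensitivity indices, and rank-stability statistics. Includes health
    outcome analytics (prevalence panels, kernel-density hotspots, global
    Moran's I with permutation inference, criterion-outcome correlation) and
    a fully synthetic scenario generator so the complete pipeline can be
    exercised without restricted health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
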