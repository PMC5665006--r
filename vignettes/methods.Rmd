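---
title: "Methods: range metrics, ensemble range models and the Red List Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range metrics, ensemble range models and the Red List Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redlisting)
```

This vignette documents the models and procedures implemented in
`redlisting`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data generators do and do not emulate.

## Range metrics

**Projection.** IUCN criterion B metrics are areas, so when records arrive
as longitude/latitude the package projects them with a spherical Lambert
azimuthal equal-area projection centred on the records' centroid, using the
authalic Earth radius (6 371 007.2 m). Equal-area distortion is the error
that matters for EOO/AOO; at the scale of a species range the planar
distances also agree with geodesic distances to well under 0.5 %. Input
already in metres (e.g. UTM) is used as-is. Autodetection treats
coordinates inside \[-180, 180\] x \[-90, 90\] as geographic; an explicit
`crs` tag overrides it.

**EOO** is the planar area of the convex hull of the sites (records, or
presence-cell centres for a predicted range). Degenerate hulls — one or
two sites, collinear sites — have zero area; in line with assessment
practice that the extent of occurrence cannot be smaller than the area of
occupancy, EOO is floored at the AOO of the same sites. The hull itself
comes from `grDevices::chull`; the area from the shoelace formula.

**AOO** counts distinct occupied cells on a fixed 2 km x 2 km grid
(4 km² per cell), the resolution IUCN mandates. The grid is anchored at
the metric origin (0, 0) and no origin or rotation optimisation is
attempted, so results are bit-for-bit reproducible; assessors comparing
against tools that slide the grid should expect this one to be slightly
conservative. Presence rasters at other resolutions map to the 2-km grid
by the *any-overlap* rule (every 2-km cell touched by a presence cell
counts). For rasters in geographic coordinates the package reprojects
presence-cell centres rather than exact cell rectangles — an
approximation acceptable at the cell sizes involved.

## Occurrence-record quality control

**Snapping** (`move_to_valid`): records on NoData cells (commonly: in the
sea, off a coastline layer) move to the centre of the nearest data cell by
Euclidean distance; everything else stays put.

**Outlier flagging** (`detect_outliers`): environmental values at the
record cells are standardized per layer *over the records* (a
record-relative statistic, matching the function's inputs — not over the
whole raster), a PCA is fitted, and each record's distance to the PC-space
centroid is reported. Records beyond `mean + 2 SD` of the distances are
flagged. The multiplier is a parameter; 2 SD is a conventional screening
default, and the flags are advisory — an assessor should inspect, not
delete. Because all components are retained, the PC distances equal
distances in the full standardized variable space; the PCA is kept for its
interpretable 2-D scatter. Records in environmentally identical cells all
sit at the centroid: zero distances, no flags.

**Spatial thinning** (`thin_records`): the threshold is a proportion of
the maximum pairwise distance among the input records (default 0.1 — no
two retained records closer than 10 % of the span). Each random run
repeatedly picks a uniformly random violating pair, deletes a uniformly
random member, and stops when no pair violates; over `runs` (default 100)
random restarts the run keeping the most records wins, ties going to the
earliest run. The deletion schedule is a design choice — greedy schedules
bias towards particular geometries, whereas random pair deletion with
restarts approaches the true maximum independent set: on instances of 10
or fewer records, 200 runs recover the exhaustively enumerated optimum in
well over 90 % of random instances. Note that two records can never
violate a threshold defined as a sub-1 fraction of their own spacing, so
2-record sets pass through intact.

## Layer reduction and habitat mapping

`reduce_layers` offers PCA scores (layers standardized over the common
data cells) or iterative correlation pruning: drop the layer with the
highest mean absolute pairwise correlation until all |r| < 0.7 (default
bound; ties drop the lowest index). Categorical and constant layers are
refused by name — a correlation or a PCA over land-cover classes is
meaningless.

`map_habitat` labels connected habitat patches and keeps those containing
records. Connectivity is queen/8-neighbour by default — diagonal-touching
habitat counts as connected, the more permissive and commoner ecological
convention — with rook/4 available as a parameter. With `move = TRUE`,
off-habitat records snap to the nearest *habitat* cell (not merely the
nearest data cell), the georeferencing-error interpretation. The output
never contains cells outside the input habitat.

## Ensemble distribution modelling

The model family is an L1-penalized logistic regression of presence
against background on linear + quadratic features of standardized
covariates — the penalized-regression formulation of maximum-entropy
presence-background modelling. This keeps the model family while removing
any external modelling program. The penalty is chosen by 5-fold
cross-validation (folds stratified so every fold sees presences; the
deviance-minimizing penalty is scaled by the `regularization` multiplier,
default 1). A fixed penalty is unusable here: under the typical 1:100
presence:background imbalance the null-model gradient, and with it the
whole useful penalty range, shifts by orders of magnitude between
datasets.

Each ensemble run redraws a 70/30 presence train/test split and a fresh
uniform background sample (default 1000 cells), fits, predicts a
suitability raster, scores the run by test AUC (Mann–Whitney form, ties
half), and binarizes at the threshold maximizing sensitivity +
specificity on the training data. What varies between runs — split and
background — is exactly what the confidence limits summarize. The
binarization rule is a parameterized choice; a fixed 0.5 cutoff is
meaningless for presence-background intensities, while max sens+spec is
the standard data-driven rule.

The **consensus map** weights each run's binary map by
`max(0, AUC − 0.5)²` and predicts presence where the weighted vote
strictly exceeds 0.5 (an exactly-0.5 cell is absent). The **confidence
limit** maps use unweighted run frequencies: cells suitable in at least
97.5 % of runs form the lower limit, at least 2.5 % the upper — weighting
applies to the consensus only, frequencies to the limits. EOO and AOO are
computed for all three maps, giving confidence limits for both metrics.
An ensemble whose runs all have AUC ≤ 0.5 carries no information and is
refused rather than silently averaged. All randomness flows from one
master seed through per-run derived seeds, so ensembles are exactly
reproducible.

## The Red List Index

Categories map to weights LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, and
EW = EX = 5 (extinct in the wild shares the top score). For one
assessment date with `N` assessable species,

  RLI = 1 − Σ w / (5 N),

1 meaning all Least Concern and 0 all extinct. Data Deficient species are
excluded from both the sum and `N` by default, as in the index's source
literature; `dd = "category"` instead treats DD as a fixed pseudo-weight
(default 2) for sensitivity analyses.

**Bootstrap.** Species are resampled with replacement, as whole rows so
assessment dates stay paired, to the original `N`; confidence limits are
the 2.5/97.5 percentiles of the replicate indices. A change between
consecutive dates is significant when *strictly more than* 95 % of
replicate changes share the sign of the observed change; an observed
change of exactly zero has no sign and is never significant, and a
replicate share of exactly 95 % does not qualify. On null tables with
identical category columns this rule fires in well under 5 % of cases —
row resampling makes replicate changes exactly zero for most draws, so
the test is conservative rather than merely calibrated. With more than
two dates every consecutive pair is tested (first-versus-last is
available by subsetting the table's columns).

**Sampled RLI.** For each subsample size `n`, random species subsets give
the distribution of |SRLI − RLI|; the error statistic is the 95th
percentile of the worst-date absolute deviation, and the reported minimal
`n` is the smallest whose statistic is within the assessor's tolerance.
Quantile and aggregation are parameters, since different programmes
tolerate different risk.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline is testable offline, and they
define the conditions under which the package's own validation runs.

* `gen_landscape` builds smoothed Gaussian random fields (separable
  kernel convolution — the simplest reproducible choice) as climate-like
  layers, an elevation surface rising toward the island interior, a
  quantile-sliced categorical land cover, and an island mask whose sea is
  NoData. Default: 100 x 100 cells of 1 km, two climate layers + elevation
  + 4-class land cover — desk-scale, mirroring the shape of a typical
  single-island assessment dataset.
* `gen_virtual_species` defines truth: suitability is the logistic of a
  linear combination of standardized layers; presence is suitability ≥
  cutoff (default 0.5). The bundled island fixture uses coefficients
  (4, −2, 1.5) with intercept −2, making the species a restricted endemic
  occupying roughly a tenth of the island. The intercept matters: a
  species occupying a third of the landscape is weakly determined — no
  model can rank presences far above background when background mostly
  *is* presence — and validation against such a species would test
  nothing.
* `gen_occurrences` samples records from presence cells, uniformly or
  clustered around a focal cell (the access-bias pattern thinning
  exists to fix), with an optional displacement error rate. The default
  of 30 records describes a moderately sampled species, the regime in
  which ensemble modelling is worth running; the island worked example
  deliberately uses only 10, one of them in the sea, to exercise the
  scarce-data path (`move_to_valid`, habitat mapping).
* `gen_category_table` draws initial categories and evolves them by a
  user-supplied Markov transition matrix; the identity matrix yields the
  null tables used to calibrate the significance test.

Real data differ in ways these fixtures do not capture: real climate
surfaces have anisotropic, multi-scale structure; real records carry
spatially *correlated* errors and detection bias toward roads and towns;
real category tables change for non-genuine reasons (taxonomy, new
knowledge) that no resampling test can separate. Passing the package's
validation therefore demonstrates correctness of the algorithms under
known truth, not that any particular real assessment is right.

## Numerical choices and problem sizes

Grids are north-up with row 1 at the top; cell (r, c) has centre
(xmin + (c − 0.5)·size, ymax − (r − 0.5)·size); points exactly on the
right/bottom edge belong to the last cell. The AOO grid anchor, the
strict consensus inequality, the strict 95 % significance inequality and
the first-best tie-breaks in thinning and correlation pruning are all
stated above; together they make every result reproducible to the bit
given a seed. Validation suites run at deliberately modest sizes — 10-run
ensembles on the 100 x 100 island, 20 replicate seeds, 200 null tables of
20 species at 1000 bootstrap replicates, 50 thinning instances of ≤ 10
records against exhaustive enumeration — sizes a reviewer can rerun in
minutes on a laptop while still leaving the stochastic acceptance bands
comfortable margins.

## Known limitations

* Hull areas are planar post-projection, not ellipsoidal-geodesic; for
  continent-spanning ranges the equal-area projection still distorts
  distances far from its centre.
* EOO from a predicted raster uses presence-cell centres, so a raster's
  EOO can sit half a cell inside an edge-to-edge reading.
* The KML dissolver may join polygons that touch only at a corner into a
  single ring (a consequence of queen connectivity at pinch vertices);
  the geometry remains valid for visualization.
* No automatic data download, no IUCN category assignment, no alpha
  hulls, subpopulation counts, or trend extrapolation: inputs are the
  user's, and the output is evidence for an assessment, not the
  assessment itself.
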