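---
title: "Habitat suitability, conservation gaps and potential range: the sdmgap workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat suitability, conservation gaps and potential range: the sdmgap workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sdmgap` implements a presence-only species distribution workflow of the
kind used to map breeding habitat for range-restricted alpine birds such
as the black-necked crane (*Grus nigricollis*): a class-balanced random
forest scores habitat suitability over a regular lattice, the continuous
surface is thresholded into a presence/absence map, and that map is
overlaid with human-pressure and protected-area layers to locate
conservation gaps and unexplored potential range.  This vignette is the
package's own account of the method: the model and its assumptions, the
parameters that matter, what the synthetic landscape does and does not
emulate, and the numerical choices behind the estimators.

## The model

Occurrence data are presence-only: confirmed nest locations, with no
usable absences.  The workflow therefore contrasts the `n1` presences
against `ratio * n1` *pseudo-absences* drawn uniformly at random from a
1,000 m background lattice spanning the study area (default
`ratio = 100`, so 183 presences face 18,300 pseudo-absences).  Lattice
cells that already contain a presence are excluded from the draw — the
source design does not state this, but sampling an "absence" in an
occupied cell would contradict its own label; the exclusion can be
switched off (`exclude_presence_cells = FALSE`).

A probability random forest (`ranger`, 1,000 trees by default) is fitted
to the labelled design.  With a 1:100 class ratio an unweighted forest
would be free to ignore the presences, so the fit uses *balanced class
weights*, `w_c = N / (2 N_c)`.  We realise the weighting as a
class-balanced bootstrap: each tree draws the same expected number of
presences and absences (sampling weights proportional to `w_c`).  Two
alternatives were considered and rejected.  Per-row case weights in the
bootstrap make every presence in-bag in essentially every tree (weight
about 50), so presences would have no out-of-bag (OOB) predictions and
internal validation would collapse.  Weighting only the splitting
criterion leaves leaf probabilities calibrated to the raw 1:100
prevalence, which breaks the useful property that an uninformative model
should score near 0.5.  The balanced bootstrap keeps OOB coverage for
every row and calibrates probabilities to a balanced prior: a forest fit
to permuted labels scores close to 0.5 everywhere, which the test suite
checks.

The fitted forest assigns every lattice cell a *relative index of
occurrence* (RIO) in [0, 1] — the presence-class probability, 0 for
confident absence, 1 for confident presence.  Scored lattice points
become a continuous raster by inverse-distance-weighted interpolation
(power 2, 12 neighbours; both exposed).  When the full lattice is scored
— the normal situation — every cell centre hosts a scored point and IDW
reduces to the identity, but the two-step flow also supports scoring a
thinned lattice and interpolating.

## Evaluation and threshold selection

Model discrimination is summarised by the area under the ROC curve (AUC)
computed from OOB scores with the rank (Mann–Whitney) formulation, ties
counted half.  A threshold table with step 0.01 records sensitivity,
specificity and the true skill statistic
(TSS = sensitivity + specificity − 1) for each cut-off; the operating
threshold maximises sensitivity + specificity, ties resolved toward the
smaller threshold, and the binary map is `RIO >= threshold`
(boundary-inclusive).  The 0.01 step matches the two-decimal precision
at which such operating points are conventionally reported.  Because the
literature is ambiguous about whether a published TSS refers to the
selected threshold or the TSS-maximising row, the pipeline reports both
(`tss_at_threshold`, `tss_max`); with sum-maximisation selection the two
coincide.

Held-out testing records never touch the fit.  Their RIOs are summarised
by the median and a percentile-bootstrap 95% confidence interval (1,000
seeded resamples — the bootstrap flavour is our choice, as the source
convention is unstated).

## Variable importance and response curves

Impurity importances are rescaled so the top variable scores exactly
100.0, the conventional presentation.  Response curves are partial
dependence: the variable of interest is clamped to each value of an
evaluation grid while all other covariates keep their observed training
values, and predictions are averaged.

Two numerical choices matter here.  First, the evaluation grid is
quantile-spaced over the training values (including min and max), so
grid points concentrate where the forest has support and the curve is
not read in data-free tails.  Second, curves can be computed on the
*odds* scale (`scale = "odds"`).  This is essential when the goal is to
read a habitat threshold off the curve.  For a presence-background
classifier with balanced classes, the Bayes-optimal probability is
`s / (s + m)`, where `s` is relative suitability and `m` the landscape
mean suitability.  When suitable habitat is rare (`m` small) this
transform saturates almost immediately, so the probability-scale curve
reaches half its height far below the true response midpoint — a bias of
several hundred metres in the elevation response of the default
synthetic landscape, affecting even a perfect model.  The per-row odds
`rio / (1 − rio)` equal `s/m`, i.e. are proportional to suitability, so
averaging odds (clipped to [0.001, 0.999] before transforming) removes
the bias.  `half_max_crossing()` then fits an isotonic regression in the
direction of the curve's trend — suppressing spurious dips — and
interpolates the crossing of the midpoint between the fitted minimum and
maximum.

Inflection recovery remains a noisy measurement at desk scale: with 183
presences on a 64 x 64 landscape the crossing of a single run has a
standard error around 150 m on the elevation response.  The package's
recovery checks therefore run three replicate landscapes and test the
per-variable *mean* crossing against the known truth (within ±10%),
which is how we recommend using the estimator in practice.

## Conservation gaps and potential areas

The gap overlay intersects three aligned rasters: the binary prediction,
a human-influence index (HII, integers 0–64; 0 = no influence), and a
protected-area mask rasterised by the cell-centre rule.  A cell is a
*conservation gap* if it is predicted presence, under meaningful human
pressure (HII at or above the safety cut-off, default 10), and outside
protected areas.  HII class shares are tabulated in five-unit bins (64
folds into the final class).  Areas are cell counts times cell area —
the grid is assumed planar and equal-area, which is what a projected
1,000 m lattice provides.

Potential (predicted-suitable but unoccupied) range is what remains of
the binary map after removing every cell within a Euclidean buffer of
known breeding records and digitised current-range polygons
(boundary-inclusive; polygon interiors are distance zero).  The
field-scale default buffer is 67 km, matching the species' within-season
dispersal capacity.  Remaining cells are aggregated into clusters by
8-connected component labelling; components below `min_pixels`
(default 10) stay unassigned, so cluster pixel counts plus the
unassigned remainder always equal the total.  A presence-pixel density
surface (disc counts divided by the full disc area, no edge correction)
ranks each cluster's focal cell — where a field survey should start.
Connectivity, minimum size and density radius mirror common GIS-tool
defaults and are all configurable.

## The synthetic landscape

Real inputs for this workflow (global bioclimatic layers, a published
HII raster, protected-area polygons, nest coordinates) are large,
licensed, or unpublished.  The `synthetic_landscape` generators make the
entire pipeline testable without them by building a virtual species on
an abstract planar landscape:

* **Covariates** are independent Gaussian random fields (white noise
  smoothed by a separable Gaussian kernel, default correlation length 6
  cells, edges mirror-reflected) rescaled to field-realistic ranges:
  `Altitude` 1,000–6,000 m, `Bio_5` (warmest-month maximum temperature)
  −5–35 °C, `Bio_4` (temperature seasonality) 2,000–12,000 units, two
  distance-type layers, and a four-class land cover with herbaceous
  cover on 40% of cells.  Altitude is skewed bottom-heavy (field^1.7):
  high plateau is the rare landform, as in real hypsometry.  `Bio_5` is
  skewed top-heavy (field^0.6): warm lowland summers dominate and the
  cool plateau tail is the limiting exception.  Together these make the
  virtual species a habitat specialist occupying a few percent of the
  landscape, which is the regime the method is designed for.
* **The truth** multiplies per-covariate responses: increasing sigmoid
  in elevation (inflection 2,800 m), decreasing sigmoid in `Bio_5`
  (20.5 °C), increasing sigmoid in `Bio_4` (7,800 units), and a strong
  herbaceous land-cover preference, scaled by a prevalence of 0.9 at
  fully suitable cells (the source gives no prevalence; 0.9 keeps
  occupancy probabilistic without flattening the signal).  Sigmoid
  scales are set so each response transitions over roughly 10% of its
  covariate's range, which keeps the inflections recoverable at desk
  scale.
* **Occurrences** are cells drawn without replacement with probability
  proportional to suitability, placed at cell centres (no jitter, so
  point-in-cell assignment is unambiguous); defaults are 183 training
  presences and 102 testing records, drawn disjointly.
* **HII** sums exponential distance-decay footprints (e-folding 5 km)
  around random settlement centres, rounded and clipped to [0, 64].
* **Protected areas** are random rectangles, each a few percent of the
  landscape, accumulated until their rasterised union reaches the target
  coverage (default 25%).

What the simulator deliberately does **not** emulate: correlation among
bioclimatic layers (each field is independent, partly so that every
response stays identifiable from partial dependence), observation bias
such as road-proximity sampling, nodata structure, and real-world
cartography.  Passing tests therefore demonstrate that the estimators
recover a known truth under clean conditions — not that any particular
real landscape satisfies those conditions.

## Problem sizes and scale choices

The default pipeline configuration runs a 150 x 150 km landscape of
1,000 m cells: the smallest extent on which the full 1/100 design (183
presences, 18,300 pseudo-absences) fits a background lattice with room
to spare.  Inflection-recovery experiments use 64 x 64 landscapes with a
1/10 design, since 18,300 absences cannot be drawn from 4,096 cells.
Two defaults are rescaled with the landscape rather than copied from the
field design: the potential-area buffer (3 km in the pipeline config —
the 67 km field buffer scaled by the ~30x difference in linear extent;
`buffer_exclude()` itself defaults to 67 km) and the settlement count
(30, which puts roughly a third of the landscape above the HII cut-off,
matching the pressure regime the overlay is meant to resolve).

## Known limitations

* Pseudo-absences are uniform background; target-group or
  environmentally stratified schemes are out of scope.
* The odds-scale response curve assumes the balanced-prior probability
  model holds approximately; heavily miscalibrated forests (e.g. tiny
  ensembles) will still bias the crossing.
* IDW with a thinned lattice is exact nearest-structure interpolation
  only in the limit of dense scoring; kriging alternatives are not
  provided.
* Buffering, rasterisation and density all use planar Euclidean
  geometry; inputs must already be in a projected, metre-based system.
* Cluster statistics depend on `min_pixels` and connectivity; the
  defaults mirror common GIS practice, not a fitted quantity.
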