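---
title: "Small-area hot-spot mapping of diabetic foot outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area hot-spot mapping of diabetic foot outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Diabetic foot ulceration (DFU), lower-extremity amputation (LEA) and the
mortality that follows them are strongly patterned by social deprivation, but
analyses at the scale of whole health regions average that patterning away.
Working at census data-zone scale — small areas holding on the order of 760
people, ranked into multiple-deprivation quintiles — lets the analysis ask a
sharper question: do zones with high outcome rates cluster *next to each
other*, and do those clusters sit in the most deprived fifth of the map?

`geofoot` implements that analysis as a pipeline: individual-level records →
per-zone numerators/denominators → crude rates → Gi\* hot/cold-spot
classification under an explicit spatial weights model → one-sample χ² tests
of spot concentration across deprivation quintiles. Because linked clinical
registers cannot be redistributed, the package also implements the study
*generator*: a synthetic geography and cohort with the statistical structure
the analysis assumes, so the full pipeline is testable end to end.

## Outcome and window definitions

Three outcome families are aggregated per zone by `aggregate_outcome()`:

* **DFU prevalence** counts any person with an ulcer on record on or before
  the window end — *previous or active* ulcer, because clinical foot-risk
  stratification is history-based. A prevalence denominator is everyone
  registered by the window end. DFU is only analysed against the 2012–2016
  window (`analysis_window("dfu_subset")`): electronic foot screening reached
  complete geographic coverage only towards the end of 2011, and earlier DFU
  data would confound spatial variation in disease with spatial variation in
  data capture. The function refuses other windows for this outcome rather
  than warning.
* **LEA prevalence** counts any amputation up to the window end over the full
  2002–2016 window; major and minor procedures are pooled (the level is kept
  on the person record but not used in aggregation).
* **Mortality preceded by DFU/LEA** counts deaths dated inside the window
  with a qualifying event on or before the death date. A same-day event and
  death counts as "preceded": registry date resolution is coarse and the
  inclusive tie-break avoids silently dropping genuine sequences.

Rates are deliberately **crude** (unstandardised): the analysis maps raw
inequality rather than adjusting it away; age/sex standardisation is a
follow-on explanatory analysis, not part of this pipeline. Prevalence is
reported in percent; mortality as incidence per 10,000 per year using the
closed-cohort approximation (person-time = population × window years, 14 for
the full window). Published outputs round to one decimal; internal statistics
never round.

## The spatial model

Data zones are physically small where population is dense and large at the
periphery. A contiguity-only neighbourhood would therefore give urban zones
systematically different neighbourhood sizes than rural ones, and a pure
distance band can leave large zones isolated. The default weights are the
**union** of:

* a **fixed distance band** on area-weighted polygon centroids, with an
  `"auto"` threshold equal to the largest nearest-neighbour distance, the
  smallest band under which no zone is isolated (the threshold actually used
  is recorded on the object and logged by the analysis scripts); and
* **queen contiguity** — zones sharing a boundary edge *or corner* — which
  corrects the band so that every pair of touching polygons counts as
  neighbours.

The union rule is a design choice: the two schemes are named as a sequence
("band, then corrected for shared boundaries"), and adding the contiguous
pairs the band misses is the correction that matches that description. Both
schemes also run standalone (`fixed_distance_band()`, `queen_contiguity()`)
for sensitivity analysis. Weights are binary, not row-standardised — the
standard convention for Gi\* with fixed-distance neighbourhoods.

Queen contiguity is detected through shared polygon vertices after snapping
coordinates to a grid of 1e-8 of the map width. Every geometry this pipeline
produces (Voronoi tessellations, grids, and polygon layers with conformal
shared boundaries) expresses edge contact through shared vertices, so this
captures both edge and corner adjacency; a T-junction where one polygon's
edge touches the interior of another's without a shared vertex would be
missed, a known limitation for badly conformed hand-digitised layers.

## Gi\* and classification

`gi_star()` implements the local statistic with self-inclusion (w_ii = 1):

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
{S \sqrt{[n \sum_j w_{ij}^2 - W_i^2]/(n-1)}},\qquad
S = \sqrt{\textstyle\sum_j x_j^2/n - \bar{X}^2}$$

computed sparsely (adjacency lists and a sparse matrix–vector product), and
verified in the test suite against an independent dense brute-force
evaluation to 1e-12 on random instances. The z-scores are treated as
standard normal — the conventional approximation for this statistic — and
binned two-tailed at 1.645/1.960/2.576 (90/95/99%); ties on a threshold take
the higher-confidence bin. Scores are invariant to shifting or positively
scaling the rate field, which the suite checks as a property.

Numerical conventions, all chosen to keep pipelines total rather than
partial:

* a constant rate field (S = 0) carries no spatial information: all z are
  returned as 0 with a warning, rather than NaN;
* a zone whose neighbourhood is the entire universe makes the variance term
  zero — genuinely undefined — and errors explicitly;
* zones with a zero denominator have no rate; they are **excluded** from the
  statistic (with their weights rows, via `subset_weights()`) and reported in
  the classification's `excluded` attribute, rather than zero-filled, since
  a structural zero would masquerade as an extreme cold rate.

No multiple-testing correction is applied by default: the mapped
classification uses raw two-tailed thresholds, which is the convention for
this kind of exploratory cluster mapping; the per-zone p-values are returned
so users can apply `p.adjust` if they want an FDR-controlled map.

## Deprivation association

`quintile_counts()` pools all significance tiers in one direction (the
hot/cold dichotomy) and counts spot zones per quintile;
`chi_square_one_sample()` tests them against expected proportions with the
textbook statistic and a χ²₄ tail. The default expected model is each
quintile's **share of data zones** rather than uniform 1/5: spots are
zone-level events and one health board's zones need not split evenly across
national quintiles. Uniform and custom expectations are available and the
model used is recorded in the result. Degenerate inputs (no spots, a zero
expected cell) error rather than returning NaN.

## The synthetic study generator

`sim_config()` defaults define the reference study conditions; they are
fixed, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_zones` | 200 | scaled-down health board (the real geography has 1,460 zones); large enough for stable global moments, small enough for fast replicates |
| `mean_population` | 760 | data-zone design population |
| `population_cv` | 0.3 | lognormal spread; data zones are built for roughly consistent size, so a moderate CV |
| `base_rates` | dfu 0.046, lea 0.013, death 0.25 | observed crude DFU and LEA rates; death is conditional on DFU/LEA history, set so absolute mortality matches the observed ~1.5% of cohort |
| `quintile_relative_risks` | 2.5, 1.5, 1.0, 0.8, 0.6 | ~4-fold spread, most- to least-deprived, the reported gradient magnitude |
| `deprivation_smoothness` | 0.15 | kernel range as a fraction of map width; produces contiguous deprived neighbourhoods without making the whole map one gradient |
| `dfu_before_lea` | 0.8 | the fraction of amputations preceded by an ulcer in routine data |

The geography is a Voronoi tessellation of the unit square with seed points
rejection-sampled to be ~4× denser at the centre, giving the small-urban /
large-rural polygon size gradient that motivates the distance-band scheme.
Deprivation is i.i.d. Gaussian noise at zone centroids smoothed by a
Gaussian kernel — a cheap stand-in for a Gaussian random field that gives
tunable spatial autocorrelation (verified in the tests against a
label-permutation null) — then ranked into balanced quintiles. Within-
quintile risk heterogeneity beyond the planted clusters is not modelled;
the knob for it is the cluster list itself.

The cohort draw couples LEA to DFU history: among amputation cases, DFU
presence is Bernoulli(0.8) with the ulcer dated on or before the amputation,
*replacing* the independent ulcer draw for those people. This shifts the
marginal DFU rate upward by roughly `p_lea × 0.8`, which is accepted: the
coupling is the only dependence structure with an empirical anchor, and the
marginal shift is small. Death is only generated for people with a DFU/LEA
history and is always dated at or after their last event, so simulated
records satisfy the aggregation invariants by construction. Event dates run
from 1 January of the start year to 7 November of the end year, mirroring a
November registry extraction.

What the generator does **not** emulate: real deprivation-index construction
(38 indicators over 7 domains — only quintile labels exist here), migration
between zones (a closed cohort, the same simplification the real linkage
makes), type 1 vs type 2 risk differences, age/sex structure, and
non-stationary data capture. Passing tests on synthetic data therefore
demonstrate that the statistical machinery is correct and calibrated — not
that any particular real geography will show a given number of spots.

## Calibration and problem sizes

The test suite and acceptance script run, on one CPU in a few minutes total:

* Gi\* sparse-vs-dense oracle agreement on 100 random instances (n ≤ 50);
* planted-cluster recovery: 100 replicates of a 200-zone flat-risk geography
  with one ×3-risk cluster of queen radius 1 — the planted centre must be
  flagged hot at ≥ 95% confidence in at least 90;
* null calibration: 40 flat-risk replicates with no clusters — the hot flag
  rate at the 90% tier should sit near the one-sided nominal 5% (≤ 10%), and
  the two-tailed significant fraction within [0.05, 0.15] of nominal 10%.
  The band is deliberately wider than binomial Monte-Carlo error because
  Gi\* z-scores are spatially correlated and zone populations are
  heteroskedastic, both of which perturb the normal approximation;
* χ² type-I error within [0.03, 0.07] at the 0.05 level over 2,000
  multinomial null tables;
* the end-to-end run under default conditions, which must concentrate hot
  spots in quintile 1 at p < 0.001.

## File formats

GeoJSON (RFC 7946 conventions: closed rings, exterior counter-clockwise,
holes clockwise; deterministic serialisation) is the canonical interchange
format; ring orientation is repaired on read with a warning since real-world
files vary. ESRI shapefile input is supported read-only through a minimal
polygon-record reader with `foreign::read.dbf` for attributes — read-only
because the format's field-name limits make it a poor write target.
Geographic (longitude/latitude) input is refused with an instructive error
based on declared CRS metadata (a GeoJSON `crs` member naming
CRS84/EPSG:4326, or a `.prj` starting with `GEOGCS`): every distance in the
pipeline is planar, and coordinate-range sniffing cannot distinguish a
planar unit square from a degree box. Maps are written as deterministic
plain-text SVG (diverging red/blue palette by confidence tier, grey
non-significant, white excluded), so rendering is testable byte-for-byte.
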