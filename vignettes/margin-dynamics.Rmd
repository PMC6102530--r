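---
title: "Measuring range-margin dynamics against realized thermal niche limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring range-margin dynamics against realized thermal niche limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginshift)
```

## The measurement model

`marginshift` operationalizes a simple but strict measurement protocol
for asking whether a breeding range margin is thermally limited.
Everything rests on one quantity: the **breeding-season temperature** of
a survey route in a year, defined as the unweighted mean, over grid
cells whose centers lie within 20 km of the route centroid, of the
April–June average of monthly mean temperatures. April–June is used
because nest-site selection responds to early-season conditions; the
20-km buffer encloses the whole of a ~39.5-km roadside route around its
centroid. A species' temperature on a route is additionally
**conditioned on observation years**: only years in which the species
was recorded there (count > 0) contribute, so the measurement reflects
conditions the birds actually bred under. A count of zero in the data is
treated as non-detection, not as a confirmed absence with measurable
conditions.

Per species and five-year period, four extreme-route sets are extracted
from the occupied routes:

* the **poleward / equatorward margin**: the k = 10 latitude-extreme
  occupied routes,
* the **cool / warm realized thermal niche limit**: the k = 10
  temperature-extreme occupied routes.

Averaging over ten routes buffers each estimate against non-detection at
any single site. Each set is summarized by the abundance-weighted mean
temperature \(T_w = \sum_i T_i c_i / \sum_i c_i\), with \(c_i\) the
species' total count on route *i* over its observation years; margins
also carry their unweighted mean latitude. The **niche centroid** is the
same weighted mean over *all* occupied routes, and the **environmental
distance** is the gap between a margin and its matching limit (poleward
margin minus cool limit; warm limit minus equatorward margin). A margin
lying at its thermal limit has distance near zero; a margin held inside
the tolerated range — by dispersal, habitat, or any non-thermal cap —
has a positive distance.

Two subtleties are worth stating plainly. First, with *unweighted* means
the environmental distances are nonnegative by construction (the coolest
ten routes minimize the ten-route mean over the occupied pool); abundance
weighting can in principle invert the ordering on unusual count
patterns, so the package reports the signed value and never clamps it.
Second, in a landscape where temperature declines strictly with latitude
the poleward margin *is* the cool-limit set and the distance is exactly
zero; a positive poleward gap is only observable because real landscapes
hold cool sites (topography) inside the range interior. The synthetic
generator mirrors both facts, and the test suite asserts them.

## Between-period shift analysis

Margins are compared across two disjoint five-year windows (defaults
1984–1988 and 2002–2006). Displacement is the change in margin-set mean
latitude converted at 111.195 km per degree (spherical meridian arc);
rates divide by the 18-year midpoint gap and rescale to a decade. Net
latitudinal extent change is the poleward-positive rate difference
`poleward − equatorward`; negative values are net contraction. The local
climate trend at the *historical* margin routes is measured over **all**
years of both periods, not observation years, because a predictor of
local extinction cannot condition on the species still being present.

The statistical battery mirrors the questions:

* `margin_limit_regression()` — OLS of (breadth-adjusted) margin
  temperature on limit temperature across species, with the slope's
  departure from the 1:1 line reported. The breadth adjustment is the
  signed deviation from the species' niche centroid; it removes
  between-species differences in niche position so that species with
  cool and warm niches are comparable. A ratio variant (deviation over
  total niche breadth) is available but not the default: the deviation
  form preserves degrees-Celsius units and the 1:1 reference
  interpretation.
* `paired_mean_difference_test()` — paired t on per-species differences
  (margin vs limit temperature, or gaps between periods). Exactly equal
  inputs give t = 0, p = 1; a constant nonzero difference is reported as
  an infinite t with a `degenerate` flag rather than an error, because
  the generator's noise-free scenarios legitimately produce it.
* `temporal_gap_regression()` — OLS of later-period environmental
  distances on historical ones plus the paired test of the mean change.
  Persistence (slope 1, nonsignificant paired t) means the margin tracked
  the moving climate; a growing gap is a climate debt.
* `shift_probability_model()` — logistic regression of the binary
  "shifted in the climatically expected direction" outcome on the
  historical environmental distance, with likelihood-ratio significance
  (the natural companion to reported log-likelihoods). Expected
  direction is poleward under local warming and equatorward under local
  cooling; zero displacement never counts as a match, and a zero
  temperature change is coded expected-poleward with a flag (the
  convention matters only for exactly-zero trends, which occur in
  noise-free simulations). Complete or quasi-complete separation is
  detected from the fitted probabilities and the fit falls back to Firth
  penalized likelihood (Jeffreys prior), flagged as such; a constant
  predictor returns a zero coefficient with p = 1 rather than an error.

Species enter the analysis only after screening: routes at or above 52°N
are dropped (sampling is too sparse further north to locate a margin);
the species' maximum occupied latitude in the historical period must be
at most 49°N, leaving at least ~330 km of sampled climate space in which
poleward expansion could be detected; and at least 100 individuals and
30 unique occupied routes are required in *each* period. The 100- and
30-thresholds are read per period (a species scarce in either window
cannot contribute a displacement), and the 49°N bound is inclusive.
Qualitative exclusions — highly disjunct ranges, principally coastal
species, non-natives — have no formula and are taken as an explicit
manual list in the configuration, never inferred from the data: guessing
a formula would silently change the species set.

## What the synthetic generator emulates

`scenario_config()` + `generate_climate()` + `simulate_observations()`
build a fully known world: survey routes on a jittered lattice; monthly
temperatures that decline linearly with latitude (default lapse 1 °C per
degree, a realistic spring gradient for mid-latitude North America) with
a configured between-period warming (default +0.43 °C, the observed
continental breeding-season change over the 18-year gap); interannual
cell noise; and two forms of spatial structure — Gaussian cell-level
heterogeneity (`spatial_sd`) and an optional **cold corridor**
(`cold_strip`), a longitude band offset several degrees colder that
spans the whole latitudinal gradient, emulating a high-elevation
interior. The corridor is what gives every species access to sites near
its cool tolerance inside the range, which is precisely the structure
that makes a positive poleward gap — a capped margin warmer than the
realized cool limit — observable and persistent. Occupancy follows a
tolerance window in buffered route temperature, plus an optional
non-thermal poleward cap; a cap may track the warming isotherm shift
(`cap_tracks_warming`), which models a species whose whole range
translates poleward even though its margin is not directly thermally
limited. Counts are shifted Poisson (`1 + Poisson(max(0, λ − 1))`) with
a log-quadratic abundance curve peaked at the thermal optimum, so a
detected presence always has count ≥ 1 and, with full detection and no
noise, the occupied set is exactly the tolerance band. Sites occupied in
period 1 suffer a persistent period-2 extinction with probability
`min(1, s · exp(−max(0, proximity)))`, where proximity is the gap to the
warm tolerance bound and `s` is the species' extinction sensitivity —
the hazard grows as the warm limit approaches, and `s = 0` disables it.

What the generator does **not** emulate: coastlines and the Gulf-of-
Mexico boundary (beyond the hard southern domain edge), observer
effects and first-year-observer biases, detection heterogeneity among
habitats, source–sink dynamics, and spatially heterogeneous warming.
Passing tests therefore demonstrate that the estimators recover known
geometry and that the tests are calibrated under the stated models —
not that real survey data are free of the confounds the screening rules
exist to blunt.

Two light-weight statistical generators accompany the landscape
simulator for calibration work at fixed n: `simulate_proximity_outcomes()`
draws per-species (distance, outcome) pairs from
`P(1) = plogis(intercept + slope · distance)`, and
`simulate_gap_pairs()` draws paired gaps with a latent between-species
component (defaults matching the observed poleward gap distribution,
2.55 ± 1.95 °C SD) plus measurement noise. Their `seed = NULL` mode
draws from the ambient RNG stream so that replicate loops are not
correlated through consecutive reseeding.

## Numerical and design choices

* **Buffer membership** is cell-center-within-20-km by great-circle
  (haversine) distance on a sphere of radius 6371.0088 km, with an
  unweighted mean over member cells. No area weighting: the rule is
  simple, testable, and at 5-arc-minute to quarter-degree resolutions
  the difference is far below the climate interpolation error. The
  route is represented by its centroid; transect geometry is not
  modeled.
* **Ties** in latitude or temperature at the k-th route are broken by
  ascending route id, making set membership deterministic across
  platforms. Fewer than k occupied routes use all routes and set a
  `small_set` flag instead of erroring, so sparse synthetic edge cases
  run.
* **Duplicate records** for the same (route, species, year) have counts
  summed with a warning; malformed rows are rejected and reported with
  file line numbers; a missing required column is fatal.
* **Reproducibility**: every stochastic component draws from
  `withr::with_seed` with fixed offsets from the scenario master seed;
  identical configurations are byte-identical, and regression tests
  assert it.
* **Problem sizes** in the shipped tests and acceptance script are
  chosen for tight feedback loops on a laptop: quarter- to half-degree
  grids over 5–20 degrees of longitude, a few hundred to ~2000 routes,
  6–12 species, and 100–1000 replicates for calibration checks. The
  estimators are vectorized over grid layers and routes, so an order of
  magnitude more of everything remains comfortable.

One scenario deserves its design note. Testing "gaps persist under pure
translation" requires per-species poleward gaps that are *reproducible*
across periods. With purely Gaussian spatial heterogeneity the measured
gap is a saturating, biased function of the true cap offset — the
coolest occupied routes fail to reach the tolerance floor, and occupancy
truncation inflates the margin temperature most for the species with the
smallest offsets — which attenuates the between-period gap regression
slope far below 1 no matter how many routes are sampled. The cold
corridor removes the artifact for the right reason: it supplies cool
sites down to every species' tolerance, pinning the realized cool limit
at the floor so the measured gap equals the cap offset up to noise. With
it, the temporal gap regression recovers slope ≈ 1 and the paired test
is null, as it should be when the whole range tracks the climate.

## Known limitations

* Margin latitude summaries ignore longitude structure; a margin that
  rotates rather than translates is summarized only through its mean
  latitude.
* Abundance weighting inherits every bias of raw survey counts; the
  fixed-site abundance supplement (`fixed_site_changes()`) exists
  precisely because such trends are not trustworthy without
  detectability corrections, and it offers the exclude-extinctions
  variant to separate real losses from non-detection.
* The logistic model uses a single predictor by design; confounds
  (range size, migratory guild) are expected to be examined by subgroup
  reruns, for which the screening report carries optional label columns.
* Environmental distances can be slightly negative under abundance
  weighting (see above); downstream analyses treat them as continuous
  signed quantities.
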