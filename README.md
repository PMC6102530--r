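# marginshift

Range-margin dynamics and realized thermal niche limits for breeding
birds, from survey-route occurrence/abundance records and gridded monthly
temperatures.

## The problem

Warming is expected to act differently at the two ends of a breeding
range: at the equatorward margin rising breeding-season temperatures can
exceed what populations tolerate, forcing local extinctions and
obligatory retraction, while at the poleward margin warming may relax a
thermal barrier and permit facultative colonization. Whether either story
is true for a species depends on where its range margins sit **inside its
realized thermal niche** — the span of breeding-season temperatures at
which the species is actually observed breeding. `marginshift` implements
the measurement and testing machinery for that question, for anyone
working with BBS-style survey data (fixed routes, annual counts) and
gridded climate:

* **Breeding-season temperature** at a route: the mean of April–June
  monthly means over grid cells within a 20-km buffer of the route
  centroid, using only the years in which the species was observed there.
* **Range margins**: the k = 10 most poleward (or equatorward) occupied
  routes of a species in a five-year period, summarized by mean latitude
  and by abundance-weighted mean temperature
  `T_w = Σ T_i c_i / Σ c_i` (route temperature `T_i`, total count `c_i`).
* **Realized thermal niche limits**: the k = 10 coolest (or warmest)
  occupied routes, summarized the same way; the **niche centroid** is the
  abundance-weighted mean over all occupied routes.
* **Environmental distance**: the temperature gap between a margin and
  its matching limit — poleward vs cool, `margin T_w − cool T_w`;
  equatorward vs warm, `warm T_w − margin T_w`.
* **Shift analysis** between two periods (1984–1988 vs 2002–2006 by
  default): margin displacement in km (Δ mean latitude × 111.195),
  per-decade rates (÷ 1.8 for the 18-year midpoint gap), net change in
  latitudinal extent, direction coding against local margin warming or
  cooling, OLS of margin vs limit temperatures (1:1 line = perfect
  correspondence), paired t-tests, temporal regression of the gaps, and a
  logistic model of shift/extinction probability on thermal proximity
  (likelihood-ratio tested, with a Firth penalized fallback under
  separation).
* **Species screening** with an audit trail: study region south of 52°N,
  historical poleward margin at most 49°N, at least 100 individuals and
  30 occupied routes per period, explicit manual exclusions.
* A **virtual-ecologist generator** that builds survey tables and climate
  grids with known ground truth: a north–south temperature gradient,
  imposed between-period warming, species with thermal tolerance windows,
  optional non-thermal poleward caps (margins held warmer than the cool
  tolerance), optional cold interior corridors, and extinction hazards
  that grow as the warm limit approaches.

## Worked example

A synthetic community of 12 species, half of them with non-thermal
poleward caps, under +0.43 °C between-period warming:

```r
library(marginshift)

cfg <- scenario_config(lat_range = c(30, 46), lon_range = c(-100, -92),
                       grid_res = 0.25, route_spacing = 0.5, lapse_rate = 1,
                       warming = 0.43, noise_sd = 0.2, spatial_sd = 1,
                       seed = 11L)
truths <- generate_species_truths(12, cfg, capped_fraction = 0.5,
                                  extinction_sensitivity = 0.3,
                                  detection_prob = 0.9)
grid <- generate_climate(cfg)
obs  <- simulate_observations(cfg, truths, grid)   # 22017 records

analysis <- analyze_range_shifts(obs, grid, cfg$period1, cfg$period2)
analysis
#> <range_shift_analysis> 12 species, historical vs modern (k = 10)
#>   poleward margin: mean shift +7.98 km/decade (sd 12.26)
#>   equatorward margin: mean shift +28.26 km/decade (sd 8.68)
```

Both margins move poleward on average, but the equatorward margin moves
much faster — half the poleward margins are pinned by non-thermal caps —
so the mean latitudinal extent shrinks by
`extent_change_rate(7.98, 28.26)` ≈ −20.3 km/decade. Gap persistence
between periods is tested directly:

```r
m1 <- subset(analysis$metrics, period == "historical")
m2 <- subset(analysis$metrics, period == "modern")
temporal_gap_regression(m1$env_distance_poleward, m2$env_distance_poleward)
#> <fit_result> temporal_gap_regression (n = 12)
#>   estimates:
#>     intercept       0.28954  (se 0.114)
#>     slope           0.58460  (se 0.1772)
#>   statistic = 3.299, df = 10, p = 0.008022
#>   R-squared = 0.5212
```

and the extinction–proximity relationship with the logistic model (here
on its calibration generator, where the generating slope is −1.5):

```r
d <- simulate_proximity_outcomes(n = 34, intercept = 2, slope = -1.5,
                                 seed = 1)
shift_probability_model(d$distance, d$outcome)
#> <fit_result> logistic_shift_probability (n = 34)
#>   estimates:
#>     intercept        1.0173  (se 1.111)
#>     slope           -2.0635  (se 0.9863)
#>   statistic = 9.219, df = 1, p = 0.002396
#>   log-likelihood = -9.588
```

A negative slope means shifts in the climatically expected direction
(e.g. marginal-population extinctions under warming) become more likely
the closer a margin sits to its realized thermal limit.

Real data enter through `load_survey_observations()` (CSV/TSV with
columns `route_id, latitude, longitude, year, species_id, count`) and
`load_temperature_grid()` (long-format CSV with `latitude, longitude,
year, month, tmean_c`), followed by `clip_study_region()` and
`filter_species()`.

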