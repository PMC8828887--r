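---
title: "Methods: cleaning, imputation and concentric-region estimation"
author: "ringmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleaning, imputation and concentric-region estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmap)
```

`ringmap` integrates three kinds of environmental monitoring data —
air-quality stations, meteorological stations and pollen traps — into
complete regional daily exposure tables. This vignette documents the models
and procedures, the tunable parameters, the numerical choices, and what the
synthetic data used in testing does and does not establish about behaviour
on real networks.

## Cleaning rules

All cleaning is deterministic, idempotent and value-destroying only (no
rule ever creates a value):

* **Pollutants** (µg m⁻³): values ≤ 0 are nonphysical and become missing
  (`clean_pollutants()`), with per-site removal counts reported.
* **Duplicate met readings**: when two networks report the same
  (site, hour), the row carrying a pressure value is kept because the
  pressure-bearing network generally has the better temperature sensor;
  with zero or two pressure values, the first row in file order is kept.
  Groups larger than two resolve by the same rule (first pressure-bearing
  row, else first row).
* **Spot stations**: a site whose every reporting day has exactly one
  temperature measurement carries no diurnal information and is removed
  wholesale before hourly imputation. One fully-sampled day anywhere in the
  record is enough to keep a site.
* **Filters**: blacklisted site ids are removed entirely (stations whose
  whole record is suspect, e.g. implausible humidity at high-altitude
  sites); any reading with temperature strictly below −20 °C has all its
  met values (temperature, dewpoint, pressure) blanked — the boundary value
  −20.0 °C itself is kept, and the co-recorded values are blanked because a
  frozen or faulty sensor taints the whole record, not just one channel.
* **Coverage selection**: coverage of a (site, measurement) is the number
  of distinct UTC days with at least one non-missing point. Defaults are
  `retain_days = 730` and `reference_days = 1278`, i.e. 2 and 3.5 years at
  365.25 days/year, floored; the durations are the primary quantities and
  the day counts are our fixed reading of them. Retention is assessed per
  measurement; reference status requires the threshold on every requested
  measurement.

## Relative humidity

RH is the ratio of actual to saturation vapour pressure,
`RH = 100·e_s(t_d)/e_s(t)`. For `e_s` we fix the Bolton (1980) Magnus form

```
e_s(t) = 6.112 · exp(17.67 t / (t + 243.5))   [hPa, t in °C]
```

because results must be bit-reproducible; any Magnus variant agreeing to
< 0.5 % RH over −40..40 °C would serve equally. Both temperatures are
required; a missing one yields missing RH. Dewpoints above the air
temperature produce RH > 100, which is *returned* (flagged via an
attribute) rather than clipped, so suspect sensors remain visible to the
cleaning filters rather than being silently normalised.

## Daily aggregation and flags

Days are UTC calendar days; partial days at the series ends aggregate over
whatever points exist. Each (site, day, measurement) gets the mean and max
of its non-missing hourly points and a flag equal to the fraction of those
points that were imputed (0 = all observed, 1 = fully imputed). A day with
no points is missing in all three columns.

## Gap imputation

Sites meeting retention coverage have their hourly gaps filled from the
`n_references = 5` nearest reference stations, by great-circle (haversine,
spherical Earth R = 6371 km) distance with ties broken by site id.
Straight-line distance is an assumption — network or travel distance might
correlate better with shared airmass in complex terrain, but nothing in the
data motivates the extra machinery.

The estimator is Bayesian ridge regression: a Gaussian prior on the
coefficients whose precision, along with the noise precision, is estimated
by evidence maximisation (MacKay fixed-point updates, Gamma(1e-6, 1e-6)
hyperpriors), so no penalty is hand-tuned. A Gaussian-prior regressor
distorts non-normal inputs, so each series is first mapped to a normal
scale:

* **quantile-normal** (default): the empirical CDF mapped onto standard
  normal scores over `min(1000, n)` quantiles. This handles the bimodal
  distributions of air/dewpoint temperature (and ozone in polluted
  locations). Values outside the training range clip to the extreme
  quantiles.
* **power** (used for pressure): Yeo–Johnson with maximum-likelihood
  exponent, then standardisation. Pressure outliers are real and the
  quantile transform clips them too harshly; the power transform preserves
  them. Inverse-transform arguments outside the representable domain are
  clipped to the domain boundary, so imputed values can never leave the
  transform's representable range.

Filling is round-robin: initialise gaps at the transformed column mean,
then repeatedly regress each gap-bearing series on all the others and
replace its missing entries with predictions, until the largest absolute
change of any imputed entry (normalised scale) falls below
`tolerance = 1e-3` or `max_iterations = 10` is reached. Non-convergence is
a warning, never an error: the last iterate is still the best available
fill. The update order is fixed (column order); with these mild shrinkage
estimators the fixed point is insensitive to order, and a fixed order keeps
runs reproducible. Observed values are restored bit-identically afterwards
and the imputation mask marks exactly the filled entries.

Orchestration (`impute_network()`): reference stations with gaps are
completed first, each against its nearest fellow references, so every
downstream regression has complete predictors; then each retained
non-reference site is filled. Meteorological measurements are imputed
independently; pollutants are co-imputed — the site's other pollutants and
its model-forecast channels (`*_EMEP` columns) join the predictor set —
because chemically linked species share information. SO₂ is passed through
unimputed by default: sparse SO₂ networks make cross-site regression
unreliable, though `impute_so2 = TRUE` remains available.

## The concentric-regions method

Regions are labelled multipolygons; two regions are adjacent iff their
geometries touch (share any boundary point without interior overlap).
Corner-only contact counts (queen contiguity): the defining notion is a
"physical boundary", a corner is one, and including corners never
disconnects the graph. Overlapping pairs are detected, reported with a
warning, recorded on the map object, and still treated as adjacent so that
estimation can proceed on imperfect cadastral data.

For a target region and day, ring k is the breadth-first shell at graph
distance k. The estimate is the unweighted arithmetic mean of all valued
sensors found in the smallest nonempty ring, averaged per *site* (not per
region first): each measurement is one piece of evidence regardless of how
sensors cluster within a ring. The ring count is reported as a confidence
proxy. Two deliberate behaviours:

* A sensor counts only when its value is non-missing at that timestamp, so
  rings expand *past* dormant stations (a pollen trap that has not started
  its season does not stop the search).
* No maximum ring count is imposed; users can threshold on the reported
  `rings_*` columns themselves. On a disconnected map the search stops at
  the component boundary and emits missing value and missing rings.

Stratified estimation reruns the identical algorithm on the sites of one
environment type (industrial, urban background, rural background, urban
traffic), with the type abbreviation spliced into the column names
(`NO2_UT_mean`, `rings_NO2_UT_mean`). The shortest-distance baseline
returns the value of the valued sensor nearest to the region's area
centroid (exterior rings only; holes are irrelevant for a representative
point at these scales) and leaves the rings column missing.

Geometries are used in geographic coordinates without projection: only the
touch topology matters to the ring method, never planar distance.

## Validation harness

* **Data removal**: withhold exactly `⌊fraction·n_observed⌋` observed
  points, randomly (seeded) or as one contiguous block at the start, middle
  or end of the observed sequence. The middle block starts at observed
  position `⌊(n−block)/2⌋` — the mode needs *some* fixed definition and the
  centred one is the natural reading. Fits are summarised by Spearman's
  rank correlation and the OLS slope (with intercept) of imputed on
  original, at hourly resolution (withheld positions only) and at
  daily-mean/daily-max resolution over *all* days, since real gap-filling
  also mixes observed and imputed points within a day.
* **Leave-one-sensor-out**: every (site, day) observation is compared with
  the concentric-regions estimate for its region computed with that sensor
  excluded; differences (sensor − estimate) are summarised by count, mean,
  std and skew. Skewness is the adjusted Fisher–Pearson sample skew
  (`e1071::skewness(type = 2)`), the common spreadsheet/pandas definition.

## Synthetic data: what it emulates, and what it does not

The generator produces grid maps of unit squares (plus islands, overlap
pairs and a two-shell demonstration topology) and sensor series of the form

```
x_i(t) = base + seasonal·sin(2πd/365.25) + diurnal·sin(2πh/24)
         + noise_sd·(√ρ·Z(t) + √(1−ρ)·ε_i(t))
```

a single shared latent factor `Z` giving every site pair correlation ρ — a
one-factor stand-in for spatial correlation that is sufficient to exercise
the imputation machinery and cheap at test scale. Pollutant-like channels
exponentiate the signal (strictly positive, right-skewed; this also makes
the nonpositive-value rule a no-op, supporting idempotence tests);
model-covariate channels are truth plus constant bias plus noise; pollen
channels are nonnegative daily counts, wholly missing outside the
configured season window (default March 1 – September 9). Generation is
bit-reproducible from the seed.

Defaults used for the correlated benchmark: 6 sites on a 5×5 grid, 90 days
hourly, ρ = 0.9, diurnal amplitude 2, seasonal amplitude 5, noise sd 1,
25 % random missingness. These sizes keep every test suite run under a
minute while giving ~2000 hourly points per series, enough for stable rank
correlations.

What passing tests on this data shows: the algorithms are implemented
correctly (oracle equivalence), observed data is never altered, and
accuracy responds to correlation structure in the expected direction. What
it does not show: performance on real networks, where correlation decays
with distance and direction, instruments drift, missingness is not
independent of weather, and pollutant sources are heterogeneous. The
one-factor world is *easier* than the real one; hourly Spearman ≈ 0.95 here
coexists with the 0.4–0.9 range seen on real pollutant data.

## Numerical and degenerate-input choices

* Geometric predicates use a 1e-9 tolerance; region metadata with duplicate
  ids or unparseable WKT fails hard, naming the row.
* Transforms refuse to fit on fewer than 10 observed points.
* Constant series yield missing Spearman correlations rather than NaN.
* Fit statistics require n ≥ 3.
* Neighbour lists supplied in region metadata are used verbatim but
  symmetrised and made irreflexive on construction.
* Sites falling outside every region polygon are excluded from estimation
  with a warning; with overlapping regions the first containing region in
  map order wins.

## Known limitations

* Polygon adjacency is O(n²) in region count with plain R loops — fine for
  national postcode-area scale (~10² regions), not for parcel-level maps.
* The imputer assumes series share one time index; mixed-frequency networks
  must be aligned first.
* No uncertainty is attached to imputed values or regional estimates beyond
  the imputed-fraction flag and the ring count.
* Topology repair is limited to rejecting invalid rings; self-intersecting
  inputs should be fixed upstream.
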