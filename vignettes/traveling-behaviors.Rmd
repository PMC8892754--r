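---
title: "Traveling behaviors and aquatic habitat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling behaviors and aquatic habitat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyforage)
```

`flyforage` studies how the traveling behavior of fish-eating migratory
birds varies with the aquatic habitat available along the route. This
vignette is the package's own account of its methods: the procedure at each
stage, the parameters that matter and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the design
choices made where the methodology was genuinely open.

## The pipeline

A migration is analysed in six stages. Raw GPS relocations are cleaned and
resampled; the track is partitioned into stopovers and traveling segments;
five behavior metrics are computed per segment; segments are annotated with
winds, weather and land cover; a randomization test asks whether the bird
sat in water-richer surroundings than chance; and linear mixed models with
information-criterion averaging relate the metrics to the annotations.

### Track processing

Fixes implying a ground speed above 150 km/h or a climb rate above 20 m/s
(against the previously retained fix) are dropped iteratively until none
remain. These thresholds are configuration, not estimates: they bound what
a large migrating bird can do, and exist to catch teleporting fixes and
altimetric spikes, both of which the synthetic generator can inject
(`gross_error_rate`).

Resampling keeps, for every 30-minute slot, the nearest observed fix
within a 5-minute tolerance and leaves other slots empty. Positions are
never interpolated: a fabricated position would manufacture plausible but
fictitious speeds, and the flight classification is speed-based. A
consequence worth knowing is that an already-30-minute track passes
through unchanged (the suite asserts this idempotence).

An interval is **flight** when the instantaneous ground speed strictly
exceeds 10 km/h at *both* its endpoints; exactly 10.0 km/h is stationary.
Device-reported speeds are used when present; otherwise the speed of the
step ending at each fix stands in, which blurs one interval at each flight
bout edge (the suite measures this: classification from device speeds
matches the generative truth exactly, step-speed classification to within
about 10%).

Solar phase uses the standard low-precision solar-position series with
sunrise/sunset at an elevation of −0.833° (refraction plus solar radius).
A fix within one hour of a sunrise or sunset event is `dawn_dusk`;
otherwise the sun's side of the horizon decides `day`/`night`. Above the
polar circles day length saturates at 24/0 h and the phase is forced
accordingly; day length plus night length is 24 h everywhere else (±1 min,
asserted).

### Segmentation

The daily displacement of day *d* is the great-circle distance between the
last relocation of day *d* − 1 and the last relocation of day *d* (the
first day is measured from the track's first fix). Days at or below
35 km/day — the threshold is inclusive — form stopovers; maximal runs of
such days become stopover records and everything between them is a
traveling segment. 35 km/day is the field's operational cut between
sedentary and migratory daily movement for large waterbirds and sits near
the antimode of observed daily-speed distributions.

Two conventions were open and are exposed as configuration:

* **Calendar days are UTC** by default (`tz` arguments throughout).
  Nothing in the method requires local solar days, and UTC days make
  multi-individual processing unambiguous; users tracking strictly
  east–west migrations at high longitudes may prefer local days.
* **Days without fixes inherit the previous day's classification.** The
  alternative — breaking segments at data gaps — manufactures spurious
  short segments out of transmitter outages.

Migration start and end are metadata supplied per track, not detected:
delineating departure from breeding or wintering residency requires
information (residency polygons, annual cycles) outside this package's
scope. The same applies to `staging_days`, the pre-departure fuelling
duration feeding `days_at_previous_stopover` of the first autumn segment.

Region assignment replaces a manual, visual step in the field's practice
with an explicit rule: the label of the polygon (editable GeoJSON
configuration) containing the plurality of the segment's relocations.

### Behavior metrics

* **Travel speed** divides the cumulative 30-min path length by the number
  of segment days — it is a rate of progress including rest, not a flight
  speed.
* **Flight height above ground** subtracts bilinearly interpolated DEM
  elevation from GPS altitude at flight fixes. The segment summary is the
  *median*: GPS altitudes carry heavy-tailed errors and a mean would chase
  them. Negative heights are retained; censoring them would bias low
  flight upward.
* **Daily flight hours** count 0.5 h per flight interval.
* **The day/night flight ratio** is, per day,
  (day flight h ⁄ daylight h) ⁄ (night flight h ⁄ dark h), then averaged
  over segment days. The photoperiod correction matters: 6 h of diurnal
  flight in a 16-h summer day is *less* diurnal preference than 6 h in an
  11-h autumn day. The exact correction formula was an open choice; this
  proportion-of-available-hours form is the one consistent with the
  ratio's stated purpose (values > 1 mean disproportionate use of
  daylight). Each interval's half hour is assigned to day or night by the
  sun's side of the horizon at the interval midpoint, which also settles
  dawn/dusk intervals. Zero day- or night-flight hours are replaced by
  0.25 h — half an interval, the resolution floor of the data — so per-day
  ratios stay finite; the magnitude is configurable.
* **Straightness** is beeline ⁄ path length, 1 for straight motion. (Note
  the index is sometimes quoted inverted; values must lie in (0, 1].)

Per-individual seasonal context is provided by `percent_change()`:
100 × (value − individual-season mean) ⁄ mean, whose group means are zero
by construction and whose lower bound is −100% for non-negative metrics.

### Environmental annotation

GPS altitude is converted to pressure with the International Standard
Atmosphere barometric formula and matched to the nearest of the eight
standard reanalysis levels (1000…300 mb). Weather fields live on a regular
lon/lat grid (2.5° by default) at 00/06/12/18 UTC. Winds are interpolated
bilinearly in space and linearly in time; all other variables are joined
only at fixes falling exactly on synoptic hours, mirroring the resolution
at which such archives are trustworthy.

Wind support uses *f*ₐ = *y* cos *θ*, where *y* is wind speed and *θ* the
angle between the bird's movement direction and the direction the air
moves *toward*. The toward-convention was an open choice; it is the one
that makes *f*ₐ a signed support term (positive when the wind blows along
the track), which is how tailwind enters the models. Crosswind is
*y* sin *θ*, signed positive when the wind comes from the bird's left;
whether crosswind should enter models signed or as magnitude is genuinely
ambiguous, so both are available (`abs()` at the call site).

Habitat availability along a segment is the proportion of cells coded as
water bodies or permanent wetlands (IGBP 17 and 11) among all cells within
5 km of the segment polyline. Buffering happens in the raster's local
metric frame (an equirectangular frame anchored at the raster origin),
which keeps distances honest at any latitude for regional rasters; the
proportion is invariant to traversal direction and stable to within 2%
under 2× grid refinement (both asserted).

### Habitat selection

The used-vs-available design: for each relocation, 99 random points are
drawn uniformly *by area* (radius ∝ √U) in a disc of radius 35, 50 or
80 km, the 5-km water proportion is measured at the relocation and at each
random point, and the one-tailed p-value is the add-one rank

p = (1 + #{null ≥ observed}) ⁄ (99 + 1),

significant at p < 0.05. The add-one rule (the observation counted among
its own nulls) is the standard unbiased Monte-Carlo test; ties count
against the observation, making the test conservative on discrete
landscapes. p therefore takes values 0.01, 0.02, …, 1.00, and the attained
level at α = 0.05 is exactly 0.04 on tie-free landscapes. The buffer radii
bracket the horizon-geometry visual range √(2·R·h): about 80 km for a bird
at 500 m.

Each relocation gets an RNG stream derived from the master seed and its
index, so batch results are reproducible regardless of evaluation order.
Relocations whose 99 nulls all tie the observation exactly (open sea,
deep desert) carry no information and are excluded from summaries. Daily
summaries stratified by solar phase × activity (flight vs stationary) feed
a binomial GLMM with individual as random effect — the GLMM itself is
delegated to `lme4::glmer`; this package owns the bookkeeping.

### Inference

Predictors are centred and scaled by one sample SD, so coefficients are
comparable effect sizes. Collinearity is screened by tolerance = 1/VIF
with VIF computed from regressing each predictor on the others; predictors
are dropped (worst first, or by stated user preference — e.g. keeping air
over surface temperature because it is the condition the bird experiences
aloft) until all tolerances reach 0.20. Responses can be Box–Cox
transformed with λ chosen by profile maximum likelihood on a grid of
−2…2 in steps of 0.05; responses containing zeros are shifted by one
hundredth of their range first, and λ and the shift are recorded for
back-transformation.

Random-effect structure is chosen once per response: the full fixed model
is fitted (REML) under each candidate structure, ranked by AICc, and the
best *non-singular* structure wins, with individual-only as the fallback.
Singularity is declared when any random-effect variance falls below 10⁻⁶
of the residual variance — a threshold made explicit here because "the fit
was singular" otherwise depends on optimizer internals.

All 2ᵖ fixed-effect subsets are then fitted by ML, weighted by
w ∝ exp(−Δ/2) under AICc or BIC (both exposed; BIC yields smaller
confidence sets on these data structures and is the default), and the
smallest weight-ordered prefix reaching 95% cumulative weight is retained
and renormalized. Coefficients are averaged by the **zero method**: a
predictor contributes 0 from models that exclude it, so the averaged
estimate equals the conditional estimate times the total weight of models
containing the predictor — a built-in shrinkage (|zero| ≤ |conditional|,
asserted on every simulation replicate). The unconditional standard error
combines within-model variance and between-model spread,
SE² = Σ wᵢ(varᵢ + (βᵢ − β̄)²), and 95% CIs use ±1.96·SE; a normal reference
is an approximation, noted as such. Spring model specifications
automatically drop days-at-previous-stopover (unmeasurable from the
tracks), precipitation and age (`season_predictors()`).

## What the synthetic data emulate — and what they do not

The generators exist to make every stage testable against known truth, not
to be realistic:

* **Landscapes** are integer IGBP-coded grids (500 m cells by default,
  the resolution of the satellite land-cover product the pipeline
  targets). Patterns are schematic: uniform speckle, a straight corridor
  band (with optional background speckle topping water up to the target
  fraction), smoothed-noise patches, and the two homogeneous extremes.
  Realized water fractions are within ±0.02 of target for rasters of
  200×200 and larger.
* **Tracks** move at a constant cruise speed along a fixed heading during
  flight intervals on a 30-min lattice, with deterministic window or
  Bernoulli-by-phase scheduling, implanted stopover days, DEM-referenced
  altitudes (Gaussian height above ground; altitude noise sd 15 m by
  default, since real devices are noisy in the vertical), optional
  position noise and gross altitude spikes. One deliberate smoothing: an
  isolated single-interval pause inside a flight bout is merged into
  flight (and recorded as such in the truth), because a 15-minute landing
  is invisible at the 30-min fix cadence; this makes the both-endpoints
  speed rule recover the truth flags exactly on noiseless tracks. The
  final half-hour of a track is held stationary so the generative truth
  never contains movement no fix could witness.
* **Weather grids** carry the eight pressure levels at 6-h steps with
  zero, constant or rotating winds (the rotating scenario exists to pin
  time interpolation to a closed form), ISA-consistent air temperatures
  and smooth random surface fields.

None of this emulates real landscapes' spatial structure, fish
availability, wind-drift interaction with heading, or behavioral feedback
between habitat and scheduling. Passing tests therefore demonstrate that
the *estimators* are correct and calibrated under known conditions — not
that real birds behave any particular way.

## Numerical choices

* Great-circle geometry on a sphere of radius 6371 km everywhere
  (haversine distances, initial bearings, destination points); the radius
  is passed explicitly to `geosphere`, whose default is the WGS84
  equatorial radius. The sub-0.5% sphere-vs-ellipsoid error is far below
  the behavioral signal at these scales.
* Rasters use an equirectangular local frame anchored at the raster
  origin; disc and buffer queries count *cell centres* and are served by
  cached row-wise cumulative sums, so a disc query costs two lookups per
  row.
* Ties in resampling (a fix equidistant to two slots) resolve to the
  earlier slot; a fix serves at most one slot.
* The segmentation threshold comparison is inclusive (≤ 35 km); the
  flight-speed rule is strict (> 10 km/h).
* Degenerate inputs: zero-variance predictors error by name in
  `standardize()`; a constant response degrades `power_transform()` to the
  identity with a warning; non-converged candidate models are excluded
  from averaging with a warning; AICc is undefined (and the model
  excluded) when n ≤ k + 1.

## The validation studies and their sizes

The seeded benchmark functions (`benchmark_*`) are the package's
calibration experiments; `scripts/acceptance.R` and the test suite run
them at these sizes, chosen to give tight Monte-Carlo error at desk-scale
runtimes (about a minute end to end on one core):

* Segmentation round-trip: 50 tracks × 14 days, with and without 1-km
  position noise.
* Metric recovery: a deterministic 6 h-day/3 h-night equatorial schedule,
  whose photoperiod-corrected ratio has closed form ≈ 2 (the −0.833°
  horizon makes equatorial daylight 12.1 h, not 12.0, so "≈").
* Randomization-test calibration: 10⁴ relocations on a selection-free
  uniform landscape. The calibration grid is 100 m rather than 500 m: an
  exact enumeration of the rank statistic over the pixel disc (binomial
  pmf) shows the conservative tie rule depresses the attained level to
  0.035 at 500 m, while at 100 m the ~7 800-cell disc makes proportions
  effectively continuous and the level is 0.039 ≈ the exact 0.04. The
  benchmark measures the test, so the grid must not confound it with
  discretization.
* Corridor power: 60 relocations pinned to the centreline of a corridor
  exactly as wide as the 5-km evaluation disc (10.1 km at 100 m cells), on
  a 10%-water landscape whose remaining water is uniform speckle. Observed
  discs are then pure water and null discs essentially never are, so the
  significant fraction sits near 1 at all three radii. Geometry note: for
  *any* corridor construction, null points near the corridor are the
  observation's closest competitors and they are *more* frequent in
  smaller availability discs, so the per-relocation rejection probability
  cannot decrease with buffer radius; a corridor benchmark can only mirror
  the buffer-monotonicity seen on real heterogeneous landscapes as a
  plateau, which is what this design produces.
* Model-averaging recovery: 100 replicates of 20 individuals × 10
  segments, true water effect −200 km/day per unit proportion, individual
  SD 30, residual SD 50, two zero-effect predictors; scores CI coverage of
  the truth, the rate at which nulls are (correctly) not flagged, and the
  shrinkage inequality.

## Known limitations

* Migration start/end and pre-departure staging are inputs, not outputs.
* The solar series is the standard low-precision approximation (events
  good to ~1–2 min); fine enough for hour-scale phase classes.
* The equirectangular raster frame distorts for continental-scale rasters
  spanning many degrees of latitude; the intended use is regional tiles.
* Non-wind weather joins only at synoptic-hour fixes; tracks resampled
  off the synoptic lattice carry no temperature/precipitation/cloud
  annotation.
* The binomial GLMM of selection summaries inherits `lme4`'s limitations
  (no overdispersion term; check residuals).
* Model-averaged CIs use a normal reference; with few individuals a
  t-style reference would be wider.
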