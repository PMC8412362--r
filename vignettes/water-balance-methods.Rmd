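---
title: "Methods: a daily Thornthwaite-type water balance and its change analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a daily Thornthwaite-type water balance and its change analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterbal)
```

## The model

`waterbal` implements a daily, single-bucket water balance of the
Thornthwaite lineage for gridded or single-site use. Each cell is
independent; each day, precipitation is tracked to one of three fates —
temporary storage (snowpack or soil moisture), evapotranspiration, or
runoff — and the diagnostic of ecological interest is the pair

* **AET** (actual evapotranspiration, mm): water actually returned to the
  atmosphere, limited by both energy and supply; a proxy for plant water
  use, and
* **CWD** (climatic water deficit, mm): `PET - AET`, the evaporative
  demand that available water could not meet; a proxy for drought stress.

The daily sequence for a cell, in fixed intra-day order:

1. **Interception.** A fraction `interception_fraction` of incoming
   precipitation is held on the canopy and evaporated the same day
   (counted inside AET); the remainder is throughfall. The default
   fraction is 0, so the feature is opt-in.
2. **Rain–snow partition.** The snow fraction of throughfall is a
   clamped linear ramp in the daily mean temperature
   `t = (tmin + tmax)/2`: all snow at or below `t50 - w`, all rain at or
   above `t50 + w`, exactly one half at `t50` (defaults `t50 = 1` °C,
   `w = 3` °C). `t50` may vary per cell through the attribute table,
   which is how spatially varying partition coefficients (they mostly
   track regional humidity differences) enter. A logistic curve with the
   same midpoint and endpoints is available behind the same interface.
   The exact published forms of the partition coefficients are cited in
   the literature rather than printed; the ramp satisfies every
   documented property of the partition and is swappable without
   interface change.
3. **Snowpack.** Same-day snowfall is added to the pack *before* melt is
   taken — a deliberate, documented ordering so results are exactly
   reproducible. Melt is temperature-index (degree-day):
   `melt = min(swe, melt_factor * max(0, t - melt_threshold))`, defaults
   4 mm °C⁻¹ day⁻¹ above 0 °C. Sublimation is not modelled separately.
4. **Potential evapotranspiration.** The Oudin formulation:
   `PET = Ra / (lambda * rho) * (t + 5) / 100` mm/day when `t > -5` °C,
   else 0, with `lambda = 2.45` MJ kg⁻¹ and water density 1 Mg m⁻³.
   `Ra` is FAO-56 extraterrestrial radiation from the solar constant
   (0.0820 MJ m⁻² min⁻¹), the inverse relative Earth–Sun distance
   `1 + 0.033 cos(2*pi*J/365)`, and the solar declination
   `0.409 sin(2*pi*J/365 - 1.39)`, recomputed every day rather than
   monthly; the sunset-hour-angle argument is clamped so polar night
   yields exactly zero. Terrain enters through a McCune–Keon-style heat
   load index from latitude, slope and aspect folded about the
   southwest axis, normalized to 1 on flat ground. The index
   multiplies the final PET. The alternative — an equivalent-latitude
   transform before the radiation integral — is not distinguishable
   from the multiplicative form by any documented behaviour of the
   method, and multiplying final PET keeps the −5 °C cutoff
   terrain-independent; this is the package's single point where that
   choice is made (`daily_pet()`), and it is flagged here because it is
   an interpretation.
5. **Vegetation scaling.** The demand presented to the soil is
   `PET * s(NDVI)`, where `s` maps the cell's daily NDVI climatology
   value linearly from `aet_scalar_min` (NDVI ≤ 0) to `aet_scalar_max`
   (NDVI = 1). The published NDVI adjustment is cited, not printed; a
   bounded linear scalar is the simplest contract satisfying it, and its
   bounds are explicit parameters. Scaling *demand* rather than reported
   PET is the most consequential interpretation in the package: AET is
   adjusted for vegetation while `CWD = PET - AET` stays literal in the
   unscaled PET. Feb 29, when it occurs, indexes the Feb 28 entry of the
   365-value climatology.
6. **Soil bucket.** With supply `w = rain + melt` and demand `d`:
   if `w >= d`, AET = `d`, the surplus recharges the bucket up to `whc`,
   and the spill is same-day runoff (no routing or delay). If `w < d`,
   the deficit draws the bucket down the exponential Thornthwaite–Mather
   drying curve, `extraction = soil * (1 - exp(-(d - w)/whc))`, so AET =
   `w + extraction` and soil water asymptotically approaches — but never
   crosses — zero. The exponential form is the canonical choice for the
   lineage and is isolated in `step_soil()`.

These rules force the invariants the tests assert: water closes exactly
(`precip = AET + runoff + Δ(SWE + soil)` to floating round-off, checked
per cell-year by `wb_mass_balance()`), `0 ≤ AET ≤ PET`, `CWD ≥ 0`,
`0 ≤ soil ≤ whc`, `SWE ≥ 0`. One caveat: with interception enabled
(non-default), interception loss is counted inside AET, so on a cold
rainy day AET can exceed PET; CWD is clamped at zero. Whether observed
AET should include interception loss is genuinely ambiguous in this
model family; the package includes it so that the water balance closes
without a separate flux term.

## Calendars, units, nodata

Both the Gregorian and the 365-day no-leap calendar (used by
Daymet-style forcing) are supported; a no-leap series is recognized by
the absence of every Feb 29 and otherwise gap-free index. Units are
mandatory metadata on read (`°C`/`K`, `mm`/`cm`/`in`); unknown units are
an error, never a guess, because unit slips dominate water-balance bugs.
Any `NA` in a day's forcing makes that cell-day's fluxes `NA` while the
carried states hold their previous values, so a nodata day does not
corrupt the rest of the run. Grids are exchanged as plain-text ESRI
ASCII rasters (row 1 = northernmost; the header is the only source of
georeferencing truth) and long-format CSV; a matrix-backed forcing
carrier (`wb_grid_forcing`) avoids materializing the long table for
large grids, and both representations produce bit-identical results.

## Initialization

Initial storages are not observable; the default starts each run with
an empty snowpack and a full bucket (`soil = whc`), which makes
first-year totals burn-in sensitive. `wb_spin_up()` offers the
principled alternative: cycle the first forcing year until the
end-of-year state converges (the maximum state change over the last
cycle is returned as a diagnostic; a handful of cycles reaches
< 0.01 mm in the test fixtures).

## Trend and change analyses

Annual totals (calendar or water year, Oct 1–Sep 30 labeled by ending
year; partial years dropped with a warning) feed four analyses:

* **Per-cell OLS trends** of annual AET and CWD on calendar year,
  computed by closed-form normal equations. Significance is deliberately
  not computed by default — the use case is broad spatial patterns of
  change, not inference — though standard errors are available via
  `se = TRUE`. The trend period and the normalizing-mean period are
  independent explicit arguments, never hard-coded.
* **Normalized change index** `(slope / mean) * 10`: the fraction of the
  period mean gained or lost per decade, stored as a fraction (×100 for
  percent display), `NA` where the mean is zero.
* **Change vectors**: the displacement of the cell's two-period mean
  position in the (CWD, AET) plane (defaults 1980–1999 vs 2000–2019),
  with Euclidean length as intensity and a sign-pair direction class;
  an exactly unchanged component is classed as increasing, and a zero
  vector is `"no change"`. Point extraction (`centroid_vectors()`) uses
  the nearest cell center and skips out-of-bounds points with a warning.
* **Bivariate zones**: a k×k classification by marginal equal-count bins
  of AET and CWD. Binning is by ranks (ties to the lower bin), which
  makes zone labels exactly invariant under monotone transforms of
  either variable — a property interpolated-quantile breaks would not
  have. How the original equal-area zones were tiled is not documented;
  marginal quantiles are one defensible reading and the one implemented.

Snow phenology per water year — first day with SWE > 0, last such day
plus one, peak SWE, count of snow-covered days — summarizes the
snowpack the same way gridded SWE products are evaluated.

## The synthetic generator

`fixture_spec()` / `make_forcing()` / `make_attributes()` generate the
study conditions every test runs on: an annual-sinusoid temperature
climate (±10 °C around a 12 °C sea-level mean, 10 °C diurnal range,
−6.5 °C km⁻¹ lapse along a synthetic elevation ramp, i.i.d. daily noise
with σ = 2 °C) and Bernoulli-gamma precipitation (occurrence
probability, gamma amounts, optional winter-peaking seasonality,
orographic enhancement, multiplicative trend floored at zero). Imposed
linear trends make estimator recovery testable. A fixed seed gives
byte-identical fixtures. Synthetic elevation exists only inside the
generator — the model itself never consumes it, only forcing and
terrain attributes.

Three named scenarios fix the package's end-to-end study conditions on
a 12 × 12 grid over 1980–2019 (a compact scale chosen once for
demonstrations and kept everywhere):

* `drying_west`: semi-arid (≈ 400 mm yr⁻¹), sparse vegetation
  (NDVI ≈ 0.35), +0.5 °C/decade warming, −3 %/decade precipitation.
  Demand outgrows supply: the median cell's CWD slope is positive.
* `wetting_east`: temperate (≈ 550 mm yr⁻¹), denser vegetation
  (NDVI ≈ 0.7), +6 %/decade precipitation, +0.1 °C/decade warming.
  Supply catches up with demand: AET rises, CWD falls.
* `alpine_gradient`: a 500–3000 m ramp with orographic precipitation
  (+80 % at the top) and elevation-dependent warming, 0.2 °C/decade at
  the base rising to 1.2 °C/decade at the top. Amplified high-elevation
  warming is a documented phenomenon in mountain climates, and it is
  the mechanism by which the combined AET:CWD change intensity grows
  with elevation here: high cells are energy-limited with ample snow
  and orographic water, so their AET tracks their strongly rising PET,
  while low cells see only the modest base warming.

What the generator does *not* emulate: spatial correlation of weather,
persistence (wet/dry spells), humidity or wind (irrelevant to a
temperature-based PET), real NDVI phenology, or real soils. Passing
tests therefore demonstrate the *mechanics* of the model and analyses —
conservation, limiting behaviour, estimator correctness, qualitative
directional response — not fidelity to any real landscape.

## Numerical choices

* State is advanced in double precision throughout; annual totals are
  accumulated on the fly, so grid runs use memory independent of run
  length. The scalar and grid code paths share one engine, and chunked
  versus unchunked execution is bit-identical (cells are independent by
  construction).
* `Ra` is precomputed per (day-of-year, cell) and the heat-load index
  once per cell; both reuse the same functions as the scalar API, so a
  1 × 1 grid run reproduces `step_cell()` exactly, bit for bit.
* Clamps: sunset hour angle to `[-1, 1]` before `acos` (polar day and
  night); the Oudin temperature drive at 0; NDVI at `[0, 1]` before the
  scalar map; CWD at 0. The heat-load regression is published for
  latitudes 30–60°; outside that range the latitude is clamped with a
  warning rather than extrapolated.
* Degenerate inputs: fewer than 3 years gives an `NA` trend with the
  count reported; a zero mean gives an `NA` normalized index; an
  all-nodata grid is an error; snow-free water years report zero snow
  days and `NA` day-of-season metrics.
* Test problem sizes (chosen once as the package's own scale): scenario
  runs 12 × 12 × 40 yr; the conservation stress test 50 × 50 × 40 yr
  (≈ 36.5 M cell-days, ~30 s single-core); estimator recovery 500
  replicate 40-year series.

## Known limitations

Single bucket, no groundwater or lateral flow; no routing (runoff is
same-day surplus); temperature-index snow without energy balance, canopy
unloading or wind redistribution; temperature-based PET only (by design
— the forcing has no wind/humidity/radiation observations); vegetation
enters only through a fixed daily climatology, so land-cover change
within a run is invisible; and the first simulated year inherits the
initialization unless spin-up is used.
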