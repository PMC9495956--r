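---
title: "Methods: a desk-scale climate impact pipeline for rice-wheat rotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale climate impact pipeline for rice-wheat rotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rotaclim` implements, at desk scale, the full chain of a multi-GCM climate
impact assessment for a rice-wheat double-cropping system: synthetic station
weather and a pseudo-GCM ensemble stand in for observational archives and a
CMIP-style model catalogue, a two-step statistical downscaling brings the
coarse monthly ensemble to station daily weather, per-scenario CO2
trajectories feed a simplified process-based rotation simulator, and
ensemble change statistics with attribution regressions summarise the
outcome. This vignette documents the models, the defaults and the design
choices, and is explicit about what the synthetic pipeline can and cannot
say about real data.

## 1. Weather model and radiation

Daily weather is the four-variable set (Tmax, Tmin, precipitation, solar
radiation). Daily mean temperature is defined as `(tmax + tmin)/2`, the
standard agro-meteorological convention. When radiation is not observed it
is reconstructed from sunshine duration with the Angstrom-Prescott relation
`Rad = (a + b * n/N) * Ra`, where `Ra` (extraterrestrial radiation) and `N`
(day length) follow the FAO-56 solar-geometry convention (solar constant
0.0820 MJ m^-2 min^-1, sinusoidal declination, sunset hour angle clamped for
polar day and night). Coefficients `a` and `b` are calibrated by ordinary
least squares of the transmissivity ratio `Rad/Ra` on `n/N`
(`calibrate_angstrom()`); the fit criterion is an assumption, since only
"calibrated against observed radiation" is ever stated for such
coefficients. The polar-night degenerate case `N = 0` returns the overcast
term `a * Ra`.

Growth-period summaries average per-season statistics over seasons; a
wheat-type window spanning the calendar-year boundary is labelled by harvest
year, and only fully covered seasons enter the average. Dates use the
proleptic Gregorian calendar with real leap years.

## 2. The stochastic weather generator

Precipitation occurrence is a first-order two-state Markov chain per
calendar month (`p01` wet-after-dry, `p11` wet-after-wet); wet-day amounts
are gamma distributed (method-of-moments fits), floored at a trace threshold
of 0.1 mm; dry days are exactly zero. Tmax, Tmin and radiation are monthly
means plus wet/dry conditional shifts plus lag-1 autoregressive residuals
whose innovations carry a fixed cross-correlation matrix (default fitted
from the series; the shipped default uses tmax-tmin 0.7, tmax-rad 0.45,
tmin-rad 0.15). This is the classical Richardson WGEN structure.

Two implementation details matter for calibration:

* **Mean-preserving wet/dry shifts.** The wet-minus-dry contrast is applied
  as `+ (1 - f) * offset` on wet days and `- f * offset` on dry days, with
  `f` the stationary wet fraction. Monthly means in the parameter table are
  therefore *marginal* means, so window averages of generated weather match
  the configured climatology regardless of rain frequency.
* **Hard physical guards.** Tmin is capped at `tmax - 0.1` degC, radiation
  is floored at zero and capped at clear-sky transmissivity (0.8 Ra).

Degenerate months are handled explicitly: a month with no wet days gets
undefined (NA) gamma parameters and generates dry days only; an all-wet
month has an undefined `p01`, recorded as 1.

The shipped climatologies for the four default stations describe a humid
subtropical monsoon climate (cold dryish winters, hot wet summers). Their
monthly values were calibrated once so that 30-year growth-period summaries
of generated weather sit inside the regional envelopes for this cropping
region: wheat season (Oct 15 - May 31) Tmax 13.9-14.8 degC, Tmin 4.3-6.7
degC, precipitation 220-472.9 mm, radiation 10.2-11.1 MJ m^-2 d^-1; rice
season (Jun 15 - Oct 5) Tmax 28.2-28.7 degC, Tmin 19.4-21.1 degC,
precipitation 567.2-654.6 mm, radiation 14-14.9 MJ m^-2 d^-1. Station-to-
station adjustments are deliberately small (within about 0.1 degC, 0.1
MJ m^-2 d^-1 and 1.5% precipitation) because the four stations span a
compact region and every station value must itself lie inside the
cross-station envelope.

## 3. The pseudo-GCM ensemble

Each pseudo-model of an ensemble draws, from a master seed expanded into
per-model substreams:

* static bias offsets (additive for temperature and radiation, sd 0.6 degC
  and 0.6 MJ m^-2 d^-1; multiplicative log-normal for precipitation, sdlog
  0.12) — these make the raw model baseline differ from the observations,
  which is precisely what makes bias correction non-trivial;
* scenario deltas from the scenario's mean and inter-model spread (additive
  warming and radiation change, multiplicative precipitation factor).

Node monthly values on a 5 x 5, 1-degree grid around the station are the
climatology plus a smooth deterministic spatial gradient, the model bias,
shared inter-annual noise, and (future window only) the model delta. Real
GCM resolutions, spatial fields, teleconnections or within-window trends are
*not* imitated; deltas are stationary per window.

**Common random numbers across windows.** The future window reuses the
baseline window's inter-annual noise realisation, so the difference between
windows is the model's delta plus nothing. Two consequences: a null scenario
(zero deltas, zero spread, zero bias) reproduces the baseline *exactly*,
giving an exact all-zero end-to-end null experiment; and imposed deltas
survive the pipeline with minimal sampling noise, which is what makes the
delta-preservation property testable at 30-year windows (warming recovered
within 0.2 degC, precipitation factor within 10%).

The default scenario specifications emulate the qualitative multi-model
pattern for the 2050s in this region: ensemble-mean warming 1.6 / 2.0 /
2.2 / 2.6 degC for SSP126 / SSP245 / SSP370 / SSP585 (spreads 0.4-0.5
degC), radiation increasing except under the aerosol-heavy SSP370 (-0.5
MJ m^-2 d^-1), and a modest precipitation increase (4-6%) with little
scenario separation.

## 4. Downscaling

The two-step chain (`downscale_model()`) is:

1. **Spatial.** Inverse-distance-weighted interpolation of node monthly
   values to the station: power 2, 4 nearest neighbours, great-circle
   (haversine) distance. Equidistant nodes split weight equally (this
   follows from the formula); a node within 1e-6 km of the target returns
   its value exactly. The node layout is static, so the weights are computed
   once.
2. **Bias correction.** Empirical quantile-quantile mapping per variable and
   calendar month, K = 30 knots (reduced to the sample size when the
   baseline is shorter), fitted on the baseline window against observed
   monthly values and applied to both windows. Between knots the map is
   piecewise linear; beyond the outermost knots the correction extrapolates
   with the constant offset of the edge pair, so future values outside the
   calibrated range are shifted, never clamped — this preserves imposed
   climate-change signals in the tails. A parametric variant was considered
   and rejected: the empirical map makes no distributional assumption and
   its identity and pure-shift behaviour are exactly testable.
3. **Temporal.** The "monthly conditioning" interpretation of a modified
   weather generator: the generator fitted to the station observations runs
   freely (Markov/AR state carried across months), then each month is
   adjusted to its downscaled monthly target — wet-day amounts rescaled
   multiplicatively to the target total (exact to 1e-9 mm), temperatures
   shifted additively to the target means, radiation rescaled
   multiplicatively and floored at zero. A month whose chain produced no wet
   day but whose target is positive gets one forced wet day at a uniformly
   chosen position, recorded in the output's `forced_wet` attribute. The
   Tmin cap is applied after the additive shift, so precipitation exactness
   is never compromised; temperature monthly means can deviate by the
   (rare) capping adjustment.

Precipitation correction operates on monthly totals, matching the monthly
resolution of the ensemble; radiation is downscaled directly rather than
reconstructed from sunshine duration. Both windows of one model use the
same generator substream (common random numbers again), so window
differences are climate signal, not generator noise.

## 5. CO2 scenario trajectories

Yearly CO2 concentrations for 1981-2070 per scenario are evaluated from
coefficient sets stored in an editable YAML configuration
(`inst/extdata/co2_coefficients.yaml`), using a small term library —
constants, shifted linear terms and shifted powers `coef * (year -
center)^degree`. The shipped defaults are a **reconstruction**: published
empirical curves of this form circulate with typographically mangled
exponents (e.g. a printed `2.4959104` standing for `2.4959e-4`), and the
leading non-polynomial terms cannot be recovered unambiguously. The
reconstruction keeps the shifted polynomial and linear terms verbatim under
the exponent decoding and represents each curve's ambiguous leading cluster
by a constant chosen so that all four scenarios pass through 340 ppm in
1981, the observed concentration at the start of the window and the shared
historical era of all pathways. The result tracks the familiar SSP
trajectories (SSP585 reaching about 560 ppm by 2041 and just under 800 ppm
by 2070).

The validation suite, not the transcription, is the acceptance surface:
every configured set must produce 90 yearly values inside a plausibility
envelope (300-1200 ppm), the four curves must agree within 10 ppm in 1981
and diverge monotonically in spread after 2015, the 2041-2070 means must
order SSP126 < SSP245 < SSP370 < SSP585, and SSP585 must be monotone
nondecreasing. A set violating the envelope raises a configuration error
naming the offending year.

## 6. The rotation crop model

The simulator is a deliberately simplified stand-in for a full cropping
systems model. It is **not** a reimplementation of any calibrated model;
every claim made by the package's tests is a claim about this model's
mechanism set: thermal-time phenology acceleration under warming, CO2
responses of radiation-use and transpiration efficiency, reproductive-period
heat stress, and irrigated rice versus rain-fed wheat.

**Phenology.** Development accumulates daily thermal time with a triangular
response on mean temperature between cardinals (wheat 0/26/34 degC, rice
8/30/42 degC — species-typical ranges; station-specific cultivar
calibrations are out of scope). Thermal-time targets are sowing-emergence /
emergence-flowering / flowering-maturity of 120/950/600 degC d for wheat and
60/1150/520 degC d for rice, chosen to put flowering and maturity in the
conventional windows (wheat flowering late April, maturity late May; rice
flowering late August, maturity around the start of October) under the
default climatology. Wheat vegetative development is modulated by
vernalization (linear accrual over 35 effective days in the 0-10 degC band,
factor = fulfilled fraction) and photoperiod (factor rising linearly with
day length below a 13 h critical photoperiod, slope 0.08 h^-1). Rice has
neither. The reproductive growth period (RGP) is flowering to maturity.

**Biomass and yield.** Canopy light interception follows
`max_cover * (1 - exp(-k * LAI))` with a thermal-time-driven LAI ramp to
flowering and a linear 50% senescence over grain fill. Biomass grows as
intercepted radiation x radiation-use efficiency (wheat 1.25, rice 1.4
g MJ^-1) x CO2 fertilization x water stress. The CO2 RUE multiplier is
linear above the 350 ppm reference (slope 7e-4 ppm^-1, capped at 1.35), a
C3-type response. Yield is biomass x harvest index (accruing at 0.012-0.013
d^-1 during the RGP, capped at 0.48/0.50) x a heat-stress factor `max(0.2,
1 - penalty * HDD)`, where HDD are degree-days of Tmax above 30 degC
(wheat) or 35 degC (rice) during the RGP — the pollination-damage
mechanism.

**Water.** A single soil bucket (default capacity 150 mm) receives
infiltration (runoff above 50 mm d^-1), drains half of any above-capacity
excess per day, supplies transpiration at up to 13% of storage per day and
evaporates from the uncovered fraction at 0.7 of potential ET. Potential ET
is a Priestley-Taylor form (alpha 1.26, net radiation proxied by 0.75 of
incoming solar, crop coefficients 1.0 wheat / 1.15 rice). Transpiration
demand is `dBiomass * VPD / (TE * co2_te)`, with TE 5.0 (wheat) and 4.0
(rice) g kPa m^-2 mm^-1 normalised at 350 ppm, VPD proxied by 0.75 of the
saturation-vapour-pressure difference between Tmax and Tmin (no humidity
forcing exists in the four-variable set), and a linear CO2
transpiration-efficiency multiplier (slope 1.2e-3 ppm^-1, the
stomatal-closure proxy). The TE slope deliberately exceeds the RUE slope so
that elevated CO2 raises biomass *and* lowers transpiration — with equal
slopes the two would cancel and ET would not fall with CO2, contradicting
the stomatal mechanism the model encodes. Supply-limited transpiration
scales the day's biomass gain (water stress); the rice flooding proxy
refills the bucket to capacity daily, which makes the supply factor
identically 1 — irrigated rice never experiences water stress, an invariant
under test. The daily balance closes exactly by construction and every
season's cumulative residual is checked below 1e-6 mm.

Seasons that fail to reach maturity before their weather segment ends are
flagged, logged and excluded from statistics rather than imputed. Nitrogen
is unlimited; pests, lodging and extreme-event damage are out of scope.
Seasonal ET is transpiration plus soil evaporation (the flooded-rice
surface is represented by the saturated bucket's evaporation; no separate
pond term).

## 7. Ensemble assessment

`run_experiment()` produces one change row per station x scenario x model x
crop (rice, wheat, total), future-window mean minus baseline-window mean.
Climate deltas use each crop's growth window; "total" rows use annual
values; the CO2 delta is the difference of annual means. Cells with more
than 20% failed seasons in either window are excluded from regressions.

Box statistics follow the multi-model plot convention: mean, median,
quartile box, 10th/90th whiskers, computed with the linear-interpolation
percentile convention.

The attribution regression `Δy = a ΔTmean + b ΔRad + c ΔPre + d Δ[CO2]` is
ordinary least squares **without intercept** — the attribution model form
contains no intercept term; an intercept variant is available behind a flag
for sensitivity. R^2 follows the no-intercept convention (total sum of
squares about zero). Pooling is stations x scenarios x models per crop: a
single coefficient set per crop is only consistent with pooling, and with
four stations, four scenarios and a 22-model ensemble that pooling yields
352 points. A per-station option exists but is unvalidated. Significance
stars are raw per-coefficient two-sided t tests at 0.05 and 0.01 with no
multiple-testing correction, matching the reporting convention the table
layout mirrors.

`sign_pattern_report()` scores significant coefficients against the
expected qualitative pattern — yield (-Tmean, +Rad, +Pre, +CO2), ET (+Rad,
-CO2), WUE (-Tmean, +CO2) — counting concordance only over significant
cells.

## 8. Problem sizes, tolerances and reproducibility

The default experiment (`run_rotation_experiment()`) uses 4 stations x 4
scenarios x 8 pseudo-models with 10-year windows — sizes chosen so the full
chain runs in a couple of minutes on a single core while leaving every
stage's statistics estimable; the pooled regressions then have 128 points
per crop. The package's own validation uses longer runs where the property
demands it: 200 years for generator round-trip recovery (monthly means
within 0.2 degC, expected monthly precipitation within 5%, transition
probabilities within 0.03), 30-year windows for delta preservation, 1000
replicated months for occurrence-chain frequencies, and 200 replicates of
n = 352 for regression coverage (per-coefficient 95% intervals covering the
truth in at least 90% of replicates).

All randomness flows from a single master seed expanded deterministically
into labelled substreams (per station, model, scenario and stage), every
stochastic output records its substream, and the whole chain is
byte-reproducible under a fixed seed.

## 9. What passing tests do and do not show

The synthetic generator reproduces marginal monthly statistics, wet/dry
persistence, wet-day skewness and short-range autocorrelation of a
monsoon-climate station, and the pseudo-ensemble reproduces the
bias/spread/delta anatomy of a multi-model archive. It does **not**
reproduce real spatial fields, interannual modes, trends within windows, or
any particular model's bias structure, and the crop simulator is a
mechanism-level stand-in, not a calibrated cropping-systems model. The
end-to-end sign concordance asserted by the tests therefore validates that
the implemented mechanisms are wired correctly through the whole pipeline —
warming accelerates phenology and depresses yield, radiation raises yield
and ET, CO2 raises yield and water-use efficiency while lowering ET — and
nothing more: quantitative magnitudes for real stations require real
forcing data and a calibrated crop model, both outside this package's
scope.
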