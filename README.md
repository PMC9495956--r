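# rotaclim

Desk-scale assessment of climate-change impacts on rice–wheat rotation
cropping: how projected changes in temperature, solar radiation,
precipitation and atmospheric CO₂ propagate — through a multi-model climate
ensemble, statistical downscaling and a process-based crop simulation — into
changes in crop phenology, grain yield, seasonal evapotranspiration (ET) and
water-use efficiency (WUE = Yield/ET).

The package is written for agro-climate researchers and students who want a
fully testable, self-contained version of this analysis chain. Archives of
observed station weather and gridded monthly climate-model output are large,
access-restricted and slow to obtain; `rotaclim` replaces them with a
first-class *synthetic* layer — a stochastic station weather generator and a
configurable pseudo-GCM ensemble — so that every downstream stage (bias
correction, disaggregation, crop simulation, ensemble statistics) runs,
and is validated, without any download. The crop simulator is a deliberately
simplified mechanism-level stand-in for a calibrated cropping-systems
model; all conclusions the package draws are about its own pipeline (see
the methods vignette, `vignettes/rotaclim-methods.Rmd`).

## The pipeline

1. **Weather core** — daily series with Tmax/Tmin/Prec/Rad; radiation from
   sunshine duration via the Angström–Prescott relation
   *Rad = (a + b·n/N)·Ra* with OLS-calibrated coefficients; monthly
   aggregation and growth-period summaries.
2. **Synthetic climate** — Richardson-type WGEN (first-order Markov rain
   occurrence, gamma amounts, AR(1) cross-correlated temperature/radiation
   residuals) fitted or configured per calendar month, and a pseudo-GCM
   ensemble whose members draw their own biases and scenario deltas
   (SSP126/SSP245/SSP370/SSP585).
3. **Downscaling** — inverse-distance spatial interpolation (power 2, 4
   neighbours) → empirical quantile–quantile bias correction per variable
   and month (30 knots, constant-offset tail extrapolation) → temporal
   disaggregation with the weather generator conditioned to match each
   downscaled monthly value (precipitation totals exact to 1e-9 mm).
4. **CO₂ scenarios** — yearly 1981–2070 concentration curves per SSP from an
   editable coefficient configuration, validated for plausibility
   (300–1200 ppm envelope, shared 1981 value, forcing-ordered 2050s means).
5. **Crop model** — thermal-time phenology (vernalization + photoperiod for
   wheat), RUE biomass with CO₂ fertilization and reproductive-period heat
   stress, transpiration-efficiency water demand with a CO₂ stomatal
   response, bucket soil water; flood-irrigated rice, rain-fed wheat;
   rotation calendar with carry-over soil state.
6. **Impact assessment** — per station × scenario × model × crop change
   rows, multi-model box statistics, and the no-intercept attribution
   regression

   ΔYield (or ΔET, ΔWUE) = a·ΔTmean + b·ΔRad + c·ΔPre + d·Δ[CO₂]

   with per-coefficient t tests, significance stars and R², plus a
   sign-concordance report against the expected qualitative pattern:
   yield (−Tmean, +Rad, +CO₂), ET (+Rad, −CO₂), WUE (−Tmean, +CO₂).

## Worked example

```r
library(rotaclim)

station <- default_station_set()$hefei
clim    <- default_station_climatology("hefei")

# 30 years of synthetic station weather
obs <- generate_station_baseline(clim, station, years = 30, seed = 42)
growth_period_summary(obs, c(10, 15), c(5, 31), crop = "wheat")
#> wheat growth period (29 seasons): Tmax 14.4 degC, Tmin 5.8 degC, Prec 428.1 mm, Rad 10.7 MJ m-2 d-1

# the rice-wheat rotation under fixed CO2
rot <- simulate_rotation(obs, co2_by_year = 380)
rot
#> rice: 30 seasons, mean yield 7820 kg/ha, mean ET 563 mm, mean WUE 13.9
#> wheat: 29 seasons, mean yield 6479 kg/ha, mean ET 385 mm, mean WUE 16.9

# a small end-to-end experiment: one station, two scenarios, 8 pseudo-GCMs
ex <- run_rotation_experiment(seed = 1,
        stations = default_station_set()["hefei"],
        specs = default_scenario_specs(n_models = 8)[c("SSP126", "SSP585")],
        years_baseline = 1981:1988, years_future = 2041:2048)
ex
#> Rotation impact experiment: 1 stations x 2 scenarios, seed 1
#>   windows 1981-1988 vs 2041-2048, 48 change rows
#>   sign concordance 100%
ex$regressions[["d_yield.total"]]
#> Delta regression: d_yield ~ dTmean + dRad + dPre + dCO2 (total, n = 16, no intercept)
#>   d_tmean    -1161.4435 ** (p = 3.97e-06)
#>   d_rad        496.0611 ** (p = 0.000537)
#>   d_pre          1.2257    (p = 0.101)
#>   d_co2          6.9168 ** (p = 0.00279)
#>   R^2 = 0.921
```

The summary lines read directly: a 30-year synthetic Hefei-like record gives
a wheat season averaging 14.4 °C daily maxima with 428 mm of rain; the
rotation yields ~7.8 t ha⁻¹ rice and ~6.5 t ha⁻¹ wheat at plausible seasonal
ET; and in the ensemble experiment, total yield change falls about
1160 kg ha⁻¹ per °C of warming while rising with radiation and CO₂ — the
expected attribution sign pattern, with precipitation (as usual for an
irrigated/humid system) not significant.

Full experiment outputs (ensemble change CSV, box statistics, regression
table, run manifest) are written by `write_experiment_report()`.

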