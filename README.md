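# urbheat

Projected warming for city populations, from multi-model gridded monthly
temperature simulations.

`urbheat` is for researchers in environmental epidemiology and climate-health
assessment who need consistent, city-level estimates of future temperature
change across a globally distributed sample of cities. It implements, as a
tested R pipeline, the standard processing chain for monthly mean
near-surface temperature (T_mean) from an ensemble of global climate models
(GCMs) run under a low and a high greenhouse-gas emissions scenario:

1. **Regridding** — each model's native-resolution global field (grids from
   64 × 128 up to 192 × 320 cells) is bilinearly interpolated to a standard
   0.5° × 0.5° latitude–longitude grid, with longitude wraparound and a
   nearest-row clamp poleward of the outermost source latitudes.
2. **Bias adjustment (delta method)** — for every grid cell, model and
   calendar month *m*, an additive offset is computed against an observed
   reference climatology over a calibration window (1961–1990):

   `offset(m, cell) = mean_obs(m, cell) − mean_sim(m, cell)`

   and added to the *entire* simulated series 1901–2100. This assumes model
   biases are stationary; any constant model bias then cancels exactly in
   all downstream temperature *changes*.
3. **City extraction** — each city's monthly series is taken from the grid
   cell containing its coordinates; cities falling in non-land cells are
   relocated to the nearest land cell by great-circle distance.
4. **Climatologies and changes** — 30-year climatological means per calendar
   month for a baseline period (1988–2017, "2017"), a near-future period
   (2021–2050, "2050") and a far-future period (2071–2100, "2100"); the
   unweighted multi-model ensemble mean of the monthly climatologies; and
   changes relative to baseline in the annual mean (mean of the 12 monthly
   values) and in the hottest- and coldest-month means, with the extreme
   months identified independently in each period.
5. **Summaries** — stratified tables of mean changes by WHO region and
   Bailey ecoregion domain, threshold-exceedance city lists (e.g. hottest
   month warming > 2 °C; hottest-month level > 40 °C), and scatter exports
   of changes against latitude, baseline seasonal range, and log₁₀
   population.

Because the real model archives are multi-gigabyte downloads, the package
ships a first-class **synthetic data module**: CMIP5-like model fields with
a latitude-dependent seasonal cycle (hemisphere phase opposition),
scenario-dependent secular warming amplified at high latitude, constant
per-model biases and independent monthly noise, plus a CRU-like land-only
reference field, a land–sea mask generator and a stratified city table. The
generator carries its own closed-form truth (`true_change()`), so the whole
pipeline is verifiable against exact answers at desk scale.

## Worked example

A one-model, five-city run on a coarse 15° grid (seconds to run):

```r
library(urbheat)
cfg <- run_config(
  n_cities = 5, models = list(mA = c(24L, 48L)),
  target_grid = global_grid(15),
  periods = list("2017" = c(1988L, 2017L), "2050" = c(2021L, 2050L)),
  sim_years = c(1960L, 2050L), ref_years = c(1960L, 2013L), seed = 4)
run <- run_pipeline(cfg)
summary(run)
#> City-mean ensemble changes relative to baseline (degC):
#>  scenario period d_annual d_coldest d_hottest
#>      high   2050     1.23      1.26      1.21
#>       low   2050     1.05      0.98      1.08

head(run$changes[, c("city_id", "scenario", "period",
                     "d_annual", "d_hottest", "d_coldest")], 4)
#>     city_id scenario period d_annual d_hottest d_coldest
#> 1 city_0001     high   2050     1.48      1.45      1.51
#> 2 city_0001      low   2050     1.28      1.27      1.30
#> 3 city_0002     high   2050     1.17      1.25      1.13
#> 4 city_0002      low   2050     1.04      1.02      1.03
```

The city-mean warming by 2050 is about 1.2 °C under the high scenario and
1.0 °C under the low one: the injected equatorial 2021–2050 warming for the
high pathway is 0.886 °C, and cities at higher latitude warm more because
of the generator's polar amplification — exactly the gradient visible in
the per-city rows. `run_pipeline()` also writes `changes.csv`,
`summary_table.csv`, exceedance lists and scatter exports plus a
reproducibility manifest to `run$out_dir`; identical configuration and seed
reproduce every file byte for byte.

A command-line wrapper with `run`, `simulate`, `regrid`, `bias-adjust`,
`extract`, `climatology` and `summarize` subcommands is installed at
`inst/cli/urbheat.R`.

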