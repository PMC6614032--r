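---
title: "Methods: city-level temperature-change projections in urbheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city-level temperature-change projections in urbheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbheat)
```

## The estimation problem

`urbheat` estimates how much warmer cities will become under low and high
greenhouse-gas emissions pathways, expressed as changes in 30-year
climatological means of monthly mean near-surface temperature (T_mean):
the annual mean, and the means of the hottest and coldest months of the
year. The inputs are an ensemble of global climate model (GCM) simulations
of monthly T_mean, 1901–2100, on heterogeneous native grids; a gridded,
land-only observational reference climatology on a 0.5° grid; a city table
with coordinates and stratification attributes; and a land–sea mask.

Working with *changes* rather than absolute temperatures, on top of an
additive bias adjustment, is the central methodological device: it removes
the stationary part of each model's bias twice over, so the result depends
on each model's simulated *warming*, not on its absolute calibration.

## Pipeline stages and their assumptions

### Grid geometry

Grids are regular in latitude and longitude, with values treated as point
samples at cell centers. Cells are half-open intervals
$[\mathrm{edge}, \mathrm{edge}+\mathrm{step})$ in both axes; a point on a
shared edge belongs to the cell starting there, which makes cell lookup
total and deterministic (the top edge of the northernmost row is closed so
every latitude in the span maps to a cell). Longitudes are normalized to
$[-180, 180)$ on input; a single internal convention avoids wraparound
bugs. The standard analysis grid is the global 0.5° grid with centers at
−89.75…89.75 and −179.75…179.75 — i.e. cell-center registration offset by
a quarter degree, matching common gridded observational products; the
registration of the analysis grid is otherwise a free choice and is
recorded in the grid object itself. The calendar is uniform (12 equal
months, gap-free series); real-archive calendar quirks are an ingest
concern outside the tested scope.

### Regridding

Each model field is interpolated to the analysis grid bilinearly among the
four source cell centers surrounding each target center, with longitude
wraparound across the dateline. Bilinear interpolation is the standard
choice for a smooth monthly temperature field, reproduces constants and
affine functions exactly, and is bounded by the contributing source values
(convexity) — properties the test suite asserts directly, alongside
agreement to $10^{-12}$ °C with an independent brute-force four-neighbour
implementation. Target centers poleward of the outermost source-center
latitude reuse the nearest source row (a clamp) rather than extrapolating
beyond data support. A nearest-neighbour method is provided mainly as a
testing oracle. Conservative (area-weighted) remapping is out of scope.

### Additive bias adjustment (delta method)

For each model, cell and calendar month $m$, the offset
$\Delta_{m} = \bar{T}^{\mathrm{obs}}_{m} - \bar{T}^{\mathrm{sim}}_{m}$
over the calibration window 1961–1990 is added to the entire simulated
series, including months far outside the window. This operationalizes the
stationarity assumption: the bias estimated in the calibration window is
taken to be the bias everywhere. Two algebraic consequences are used as
tests: *calibration closure* (after adjustment, each month's 1961–1990
mean equals the reference exactly, up to floating-point round-off — the
suite asserts $<10^{-9}$ °C, observed $\sim10^{-14}$) and *bias
cancellation* (adding any constant to a model series leaves every
downstream change invariant; asserted at $10^{-12}$ °C, the double-precision
round-off floor of the climatology means — exact zero is not attainable in
floating point because the offset computation re-associates the sums).
Cells missing in the reference (ocean) propagate missing rather than
falling back to unadjusted values: silently mixing adjusted and unadjusted
data would corrupt comparisons. The calibration window ends before the
baseline period begins; no observational blending is applied after 1990.

### City extraction

A city takes the series of the grid cell containing its coordinates. If
that cell is not land in the mask, the city is relocated to the land cell
whose center minimizes great-circle (haversine) distance — index-space
distance would be wrong near the poles where meridians converge. The rule
applies whenever the city's cell is non-land, coastal or otherwise, since
a non-land cell is the only way it can trigger. Exact distance ties break
to the lowest latitude index, then lowest longitude index, for
reproducibility. The relocation is verified against an exhaustive
great-circle scan over all land cells (with an independent distance
implementation) on a thousand random city/mask draws.

### Climatologies, ensemble, changes

For each period (baseline 1988–2017 "2017", near future 2021–2050 "2050",
far future 2071–2100 "2100") the 12 climatological monthly means are
simple 30-year averages; the annual mean is the mean of the 12 values; the
hottest/coldest months are the extremes of the 12 (earliest month wins
ties). Two genuinely open design choices arise and both alternatives are
implemented:

* **Extreme months per period or fixed at baseline.** Default: identified
  independently in each period, matching the plain reading of "the hottest
  month of the year" in each epoch — the hottest month may shift (e.g.
  July to August). `extreme_month = "baseline"` fixes the baseline months
  instead.
* **Ensemble before or after extremes.** Default: the unweighted model
  ensemble is formed on the monthly climatologies first, then extremes are
  identified on the ensemble seasonal cycle — this avoids averaging
  extreme values taken in different months across models.
  `ensemble = "after_changes"` computes per-model changes first and
  averages those. The two orderings agree exactly for annual means
  (linearity) and agree for extreme-month changes whenever the models
  share the seasonal shape; both identities are asserted in the suite.

Stratum summaries are unweighted means over the cities of each
(WHO region × ecoregion domain) stratum; exceedance lists use strict `>`
for "greater than"/"exceed" phrasing, with the operator configurable since
boundary handling is a convention. Missing-attribute exclusion is
per-analysis, not global: a city without a population value is excluded
from the population export but kept everywhere else.

## The synthetic-data generator

The generator defines the desk-scale study conditions. Monthly temperature
at a cell with center latitude $\phi$, month $m$, year $y$, model $i$,
scenario $s$ is

$$T = \mu(\phi) + A(\phi)\cos\!\frac{2\pi(m-p(\phi))}{12}
  + \delta_s\, w_s(y)\, a(\phi) + b_i + \varepsilon,$$

with mean profile $\mu(\phi) = 28 - 48(\phi/90)^2$ °C (warm equator, cold
poles), seasonal half-range $A(\phi) = 20\,|\phi|/90$ °C peaking in July
north of the equator and January south of it (phase opposition), polar
amplification $a(\phi) = 1 + 2(\phi/90)^2$ (poles warm three times the
equator), constant model biases $b_i$ (the stationarity assumption made
literal), and independent noise $\varepsilon \sim N(0, 0.5^2)$ °C per
month and cell. Noise autocorrelation is irrelevant to the recovery of
30-year means at the tested tolerance, so none is simulated.

The scenario trajectories are monotone shapes $g_s(y) \in [0,1]$ — a
linear rise from 1990 to a plateau at 2050 for the mitigation-like "low"
pathway, a quadratic acceleration through 2100 for the business-as-usual
"high" pathway — rescaled to
$w_s(y) = (g_s(y) - \bar g_B)/(\bar g_F - \bar g_B)$, where $\bar g_B$ and
$\bar g_F$ are the trajectory means over the baseline (1988–2017) and
far-future (2071–2100) windows. With this calibration $\delta_s$ *is* the
realized equatorial far-future warming, so the defaults
$\delta_{\mathrm{low}} = 1.10$ °C and $\delta_{\mathrm{high}} = 4.15$ °C
make default runs echo headline end-of-century magnitudes for strong
mitigation versus business-as-usual. These are generator settings, not
reproduction claims. Warming shifts the mean level only — by default the
seasonal amplitude does not change, which is why the injected change is
simultaneously the truth for annual, hottest-month and coldest-month
changes; an optional `seasonal_sharpening` knob scales the amplitude with
warming but defaults off, since 30-year monthly means are not very
sensitive to distributional tails. `true_change()` exposes the closed-form
injected change between any two whole-year windows.

The reference field uses the same equation with $b = 0$ (the reference is
unbiased truth plus observation noise), masked to land. The land mask
generator offers all-land, a deterministic continent-band pattern, and
"random blobs" (a thresholded, bilinearly upsampled coarse random field,
hitting a configured land fraction). The city generator uses proportional
largest-remainder allocation for the stratification axes — a stratified
design fixes stratum counts; the seed only shuffles assignments — and
draws latitudes from domain-consistent bands (polar 60–85°, dry 15–45°,
humid temperate 30–60°, humid tropical 0–23.5°; 75 % northern hemisphere),
longitudes uniformly, and populations log-uniformly above the 15,000
floor.

What the generator does *not* emulate: realistic coastlines, internal
variability structure (ENSO, volcanism), model-to-model disagreement about
the *pattern* of warming (all synthetic models share $a(\phi)$ and differ
only by bias and noise), humidity, daily extremes, or urban heat island
effects. Passing tests therefore demonstrate that the pipeline's
*algebra* — interpolation, offset arithmetic, relocation, averaging,
differencing, stratification — is correct and bias-invariant; they do not
validate any claim about real-world warming rates.

## Numerical choices and problem sizes

Exact recovery in the noiseless limit (observed error $\sim10^{-15}$ °C,
asserted at $10^{-9}$) is checked with model sources on the analysis grid,
where the bilinear weights degenerate to an exact identity. This isolates
the adjust/extract/climatology algebra from interpolation error, which is
$O(h^2)$ for the smooth quadratic amplification profile (about
$2\times10^{-3}$ °C at a 2.8° source resolution) and has its own analytic
and brute-force oracle tests. The noisy default study — 6 models on native
grids from 64 × 128 to 128 × 256, 2 scenarios, 50 cities, monthly
1901–2100 on a 2° analysis grid — recovers per-city ensemble annual
changes within ±0.1 °C of closed-form truth: the standard error of a
30-year × 12-month mean difference averaged over 6 models is
$\sqrt{2 \cdot 0.5^2/360/6} \approx 0.015$ °C, so 0.1 °C is a
conservative bound for every city. The 2° analysis grid (rather than the
full 0.5° standard grid, which the geometry and regridding code support
and test) keeps a 2400-month global field at ~300 MB and the whole study
in minutes on one CPU; all pipeline algebra is resolution-independent.

Reproducibility: a single root seed yields deterministic per-stage
sub-seeds (cities, mask, reference, each model × scenario field); seeded
generators restore the caller's RNG state. Identical configuration and
seed reproduce every output file byte for byte, and the manifest (config
echo, package version, per-stage record counts, no timestamps) suffices
to re-run the pipeline to identical bytes.

Gridded fields serialize to a self-describing plain-text format
(`write_field()`/`read_field()`) that round-trips doubles exactly; tables
are CSV and truth/config parameters are YAML, so every stage is
independently runnable and resumable from files (see the command-line
wrapper in `inst/cli/`).

## Known limitations

* Monthly means carry no information about changes in daily extremes or
  heatwave structure; an upward mean shift is the only signal propagated.
* Single-cell extraction ignores city footprints and population weighting;
  at coarse model resolution neighbouring cities can be indistinguishable
  and coastal cells biased — consequences the focus on changes mitigates
  but does not remove.
* The additive adjustment corrects means only (no quantile mapping or
  variance scaling), and its stationarity assumption is untestable from
  within the data.
* Synthetic-model spread understates structural uncertainty of real
  ensembles, so recovered ensemble spreads should not be read as
  projection uncertainty.
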