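---
title: "Estimating macroalgal canopy biomass from paired light loggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating macroalgal canopy biomass from paired light loggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Fucoid and kelp canopies are productive, seasonally dynamic habitats, but
their biomass is awkward to monitor. Percentage cover saturates at 100%
long before biomass does (multilayered canopies), harvests are destructive,
and most monitoring programmes sample annually at best, so the seasonal
build-up and decline of biomass is rarely observed.

`canopylux` implements a light-attenuation proxy. Inexpensive lux loggers
are deployed in pairs of roles on the same shore height: some under 100%
canopy cover, some on adjacent open rock. The canopy intercepts light
before it reaches the under-canopy sensors, and the *relative* attenuation
between the two roles is a biomass proxy that can be logged every half
hour for a year on consumer hardware.

## The model

Light at the seabed is modelled with a Beer-Lambert approximation. Under a
canopy,

$$I_c = I_s\,e^{-k_w z - k_a T_{AI}},$$

and on open rock,

$$I_o = I_s\,e^{-k_w z},$$

where $I_s$ is surface light, $k_w$ (m$^{-1}$) the attenuation coefficient
of seawater, $z$ (m) the water depth over the sensors, $T_{AI}$ the
thallus area index (m$^2$ frond per m$^2$ seabed, >1 for multilayered
canopies) and $k_a$ (per unit $T_{AI}$) the canopy attenuation
coefficient. For sensors at the same depth in the same water body, taking
logs and subtracting cancels $I_s$, $k_w$ and $z$:

$$\ln\!\left(\frac{I_o}{I_c}\right) = k_a T_{AI}.$$

This is the attenuation index computed by `attenuation_index()`. Its
crucial property — the reason the method tolerates tides, turbidity
changes and weather — is that the water column and surface light drop out
entirely. The index is unit-free, so any consistent intensity unit works
(lux from consumer loggers, PAR from quantum sensors), although $k_a$ may
depend on the sensor's spectral response.

Assumptions worth stating explicitly:

* both roles see the same water depth and the same water mass (sensors
  interspersed at one shore height, metres — not hundreds of metres —
  apart);
* $k_a$ is constant over the deployment. Fucoid pigment content rises in
  winter, which would inflate apparent $T_{AI}$ in winter if real; the
  package deliberately keeps $k_a$ a single calibration constant
  (`calibration_params()`) rather than inventing a seasonal model for it;
* the canopy over the under-canopy sensors stays at effectively full
  cover, so the index tracks layering (biomass), not patchiness.

## From raw loggers to an index series

`compute_index_series()` chains the ingestion and filtering steps; each is
also exported on its own.

1. **Alignment** (`align_to_grid()`). Records snap to a shared grid
   (default 30 min) when within a 5-min tolerance; nothing is
   interpolated. Slots a sensor missed become `NA`.
2. **Fouling masks** (`apply_mask_windows()`). Site-visit notes become
   half-open `[start, end)` windows whose light values are discarded.
   Half-open intervals compose without double-masking at boundaries.
3. **Open reference** (`mean_open_series()`). $I_o$ is the per-timestamp
   arithmetic mean over whichever open sensors report. Exposed loggers
   fail and foul more often than sheltered under-canopy ones; the
   mean-of-available rule uses what survives, with `coverage_report()`
   showing how much that was. No imputation.
4. **Night/zero filter**. `ln(I_o/I_c)` is undefined when either reading
   is zero (every night, for a lux logger), so timestamps where either
   value is missing or at/below `light_threshold` (default 0 lux, i.e.
   strict positivity; raise it for sensors with a noise floor) become
   missing — never an error, and never a clipped value. Negative indices
   from noise are *retained* so that smoothing stays unbiased.
5. **Crepuscular filter** (`crepuscular_filter()`). Empirically the index
   dips near dawn and dusk (low-light sensor behaviour and a changing
   diffuse/direct balance are both plausible mechanisms). Each timestamp
   is mapped to its daylight fraction (dawn = 0, dusk = 1) and the first
   and last tenth (`crepuscular_fraction = 0.1`) of daylight are dropped.

Solar geometry for step 5 comes from a standard Fourier-series ephemeris
(declination + equation of time). Dawn/dusk default to the sun-centre
zero-elevation crossing without refraction; `refraction = TRUE` switches
to the conventional 90.833° rise/set zenith. At a 10% trim the choice is
immaterial — the two conventions differ by a few minutes — but it is a
config switch, not a hidden constant. Timestamps are naive clock times;
the site's longitude and UTC offset correct clock noon to solar noon
(~37 min at 9.2°W), without which the daylight-fraction axis would be
skewed.

Day-of-year is fractional with 00:00 on 1 January = day 1.0 (noon on
12 June of a non-leap year is day 163.5), continuing past 365 across a
year boundary so a deployment has one monotone axis.

## The seasonal trend fit

`canopy_trend()` is the model fit of the package: a LOESS smooth of index
against day of year per under-canopy sensor, evaluated on a daily grid,
with peak/trough value and day per sensor and a cross-sensor mean ± SE
(sample SD/√n; with one sensor the SE is reported missing).

* **Span 0.4, degree 1, tricube weights, no robustness iterations** are
  the defaults. Canopy biomass changes gradually — growth, erosion and
  senescence act over weeks — so the smoother should track a seasonal
  wave and ignore weather; 40% of a year-long record is a window of that
  scale. Degree and robustness iterations (0 or 2) are exposed for
  tuning on real data.
* The span counts *present* points, since missingness differs by sensor
  and season (short winter days contribute fewer daylight points).
* The implementation (`loess_smooth()`) fits the `ceiling(span·n)`
  nearest neighbours at each evaluation point by tricube-weighted least
  squares. It reproduces `stats::loess(surface = "direct")` when span·n
  is integral; it exists so the neighbourhood rule is explicit, testable
  against a hand-coded weighted-regression oracle, and cheap to evaluate
  on a daily grid.
* **Aggregation.** By default the half-hourly retained points are
  smoothed directly (the dense-point-cloud view of the data);
  `aggregate = "daily-median"` pre-aggregates per day, which is faster
  and robust to within-day weather at the cost of within-day
  information. On noise-free synthetic data the two agree closely.
* **Extrema** are argmax/argmin on the daily grid with ties broken by the
  earliest day. A local-linear smoother can overshoot the observed range
  slightly at record edges; extrema are reported from the smoothed
  series as-is.

With `k_a` supplied, summaries are also reported on the $T_{AI}$ scale
(`index / k_a`). The package default `k_a = 0.7` is the published
mid-range value for fucoids; measured values should replace it whenever
available. `wet_weight_to_tai()` closes the loop with harvest data via
`T_{AI} = \mathrm{wet\ weight} \times (1 - \mathrm{water\ content})
\times \mathrm{specific\ thallus\ area}`; the bundled
`specific_thallus_area_defaults` are back-calculated reconstructions
(flagged as such in their documentation), not measurements.

## The synthetic light climate

`simulate_deployment()` exists so every stage above can be validated by
parameter recovery against known truth. It composes:

* **Surface light**: clear-sky illuminance ∝ max(0, sin(solar elevation))
  scaled to a 100 klx noon peak, times a median-preserving lognormal
  cloud factor (σ = 0.4) whose log is AR(1) with a 6 h decorrelation
  time;
* **Tide**: M2 (12.42 h) + S2 (12.00 h) cosines, amplitudes 1.55 m and
  0.95 m over a 0.9 m mean, clamped at zero. The constituent beat gives a
  ~1.2 m neap to ~5 m spring range, matching the Galway Bay setting the
  defaults emulate; the clamp represents sensors drying out at low tide;
* **Canopy**: $T_{AI}(t)$ as an annual cosine, default 4.5 ± 1.5 peaking
  on day 195, attenuating with $k_a = 0.7$;
* **Sensors**: independent multiplicative lognormal noise per reading
  (σ = 0.5 on both roles) emulating wave lensing on open rock and sun
  flecks / frond movement under canopy, then a 1 lux detection floor and
  1 lux quantization. Multiplicative lognormal noise is the deliberate
  choice: it is heavy-tailed like wave lensing, and on the log-ratio
  index it becomes *additive, symmetric and mean-zero*, so the smoother
  sees unbiased scatter.

What the simulator does **not** emulate: the spectral response of real
lux sensors (no wavelength resolution anywhere), cosine-response error,
the diffuse/direct light balance, fouling growth, patch-edge light
leakage, or real multi-constituent tides. Recovery of the biomass cycle
from synthetic deployments therefore demonstrates that the *pipeline* is
correct and that the index cancels the water column exactly as the
algebra promises — it does not certify the physics of any particular
sensor on any particular shore. An optional crepuscular sensitivity
rolloff is off by default because the mechanism behind the real dawn/dusk
dip is speculative.

Validation sizes used by the package's tests: noise-free 3-day
deployments over a 3×3×3 grid of surface light × turbidity × tide
settings for the cancellation identity (machine precision); twenty
one-year, 30-min, 4+4-sensor deployments at the default noise for cycle
recovery (peak day within ±10 days of 195, peak index within ±10% of
4.2 in ≥18/20 replicates — observed 20/20).

## Sensor drift diagnostic

`drift_check()` mirrors the field diagnostic for logger degradation:
regress daily mean exposed-sensor light on an independent daily reference
radiation series, then regress the residuals on date. Stable sensors give
a residual-date $r^2$ near zero; a sensitivity loss leaves a negative
date trend. When the first regression is numerically exact the residual
regression is reported as zero rather than fitting floating-point noise.

A power caveat discovered during validation: a multiplicative decay
produces residuals equal to the decay curve *times the reference*, and a
seasonally peaked, weather-modulated reference concentrates that product
away from a straight line in date. The linear residual-date $r^2$ for a
30%/year decay over a year at 53°N is therefore modest (~0.1 under
deployment-like conditions) even though the decay is obvious in the
residual trend and its slope. Treat the residual-date *slope and its
significance*, not the $r^2$ magnitude, as the detection signal; the
no-decay control stays well below $r^2 = 0.05$ in all conditions tested.

## Known limitations

* $k_a$ is the calibration bottleneck: it varies with species, season
  (winter pigment increase) and sensor spectral response, and published
  values are scarce. Without it the method still yields a consistent
  relative biomass proxy.
* The method loses sensitivity at very low biomass (little interception)
  and saturates at very high biomass (little light under the canopy and
  a noise-floor-limited denominator).
* Point measurement: each sensor pair characterises square metres, not a
  shore; the hierarchical patch structure is carried in metadata but not
  modelled.
* Naive clock-time handling assumes the deployment does not straddle a
  DST change in the logger's own clock; loggers are normally run on a
  fixed offset.
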