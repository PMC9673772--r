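# canopylux

Seasonal macroalgal canopy biomass from paired light loggers.

Fucoid and kelp canopies are monitored worldwide, but biomass is the hard
part: percentage cover saturates at 100% while multilayered canopies keep
adding biomass, and harvest quadrats are destructive. `canopylux`
implements a non-destructive proxy for ecologists running shore
deployments of inexpensive lux loggers: some sensors under full canopy
cover, some on adjacent open rock at the same shore height.

## The model

Light at the seabed follows a Beer-Lambert approximation. Under a canopy
and on open rock respectively,

```
I_c = I_s · exp(−k_w·z − k_a·T_AI)        I_o = I_s · exp(−k_w·z)
```

with surface light `I_s`, seawater attenuation `k_w` (m⁻¹), water depth
`z` (m), canopy attenuation coefficient `k_a` and thallus area index
`T_AI` (m² frond per m² seabed). Because both sensor roles share the same
water column, the log ratio cancels everything except the canopy:

```
ln(I_o / I_c) = k_a · T_AI
```

This attenuation index is computed every daylight half hour, filtered
(night zeros make the ratio undefined; the first and last tenth of
daylight are unreliable and trimmed), smoothed against day of year with a
LOESS (span 0.4) per sensor, and summarised as seasonal peak/trough value
and timing across sensors. Given `k_a` (published mid-range for fucoids:
0.7 per unit `T_AI`), the index converts to thallus area index;
`wet_weight_to_tai()` connects it to harvest biomass.

The package also ships a synthetic intertidal light-climate simulator
(diel/seasonal sun, AR(1) lognormal cloud, M2+S2 spring–neap tide,
seasonal biomass cycle, multiplicative sensor noise, lux floor and
quantization) with known ground truth, so the entire pipeline is
validated by parameter recovery.

## Worked example

Simulate a year-long Galway Bay-like deployment (4 open + 4 canopy
sensors, 30-min sampling, thallus area index cycling 4.5 ± 1.5 with its
peak on day 195, heavy sensor noise), then run the analysis exactly as
for field data:

```r
library(canopylux)

cfg <- sim_config(seed = 42)
sim <- simulate_deployment(cfg)

idx <- compute_index_series(sim$loggers, sim$sensors, cfg$site)
fit <- canopy_trend(idx, span = 0.4, k_a = 0.7)
summary(fit)
#> Seasonal canopy trend (LOESS span 0.40, degree 1)
#> Per-sensor extrema:
#>           peak_value peak_day trough_value trough_day
#> canopy_01      4.243      192        1.905          2
#> canopy_02      4.219      192        1.936          2
#> canopy_03      4.216      192        1.988          2
#> canopy_04      4.225      192        1.954          2
#>
#> Across 4 sensor(s) (mean, SE = sd/sqrt(n)):
#>      peak_value peak_day trough_value trough_day
#> mean      4.226      192        1.946          2
#> se        0.006        0        0.017          0
#>
#> Thallus area index scale (k_a = 0.70):
#>      peak_value peak_day trough_value trough_day
#> mean      6.037      192        2.780          2
#> se        0.008        0        0.025          0
```

The generator's truth is a peak index of 0.7 × 6.0 = 4.2 on day 195: the
pipeline recovers 4.226 ± 0.006 on day 192 despite lognormal σ = 0.5
noise on every reading. (The trough sits at the record edge because the
simulated year starts at the cycle minimum.) `plot(fit)` draws the point
clouds and trends; `predict(fit, days = ...)`, `coef(fit)`,
`fitted(fit)` and `residuals(fit)` behave as for any fitted model.

Field data enter the same way via `read_logger_csv()`,
`read_sensor_meta()` and optional fouling windows (`read_mask_windows()`),
or from the shell:

```sh
Rscript inst/cli/canopylux.R simulate --out run/
Rscript inst/cli/canopylux.R report --loggers run/loggers.csv \
    --sensors run/sensors.csv --out run/ --k-a 0.7
```

`drift_check()` regresses daily mean exposed-logger light on a reference
radiation series (e.g. a nearby met station) and then its residuals on
date, to confirm sensors did not lose sensitivity over the deployment.

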