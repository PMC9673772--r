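test_that("canopy_trend recovers a noiseless seasonal cycle end-to-end", {
  # 120 days around the biomass peak, no noise anywhere: the smoothed
  # trend must ride on the true k_a * TAI(t) curve and peak at the
  # generator's peak day within one grid step
  cfg <- quiet_config(n_days = 120, start_date = "2019-05-01", seed = 5)
  sim <- simulate_deployment(cfg)
  idx <- compute_index_series(sim$loggers, sim$sensors, cfg$site)
  fit <- canopy_trend(idx, span = 0.4, k_a = cfg$canopy$k_a)
  expect_s3_class(fit, "canopy_trend")
  expect_equal(length(fit$fits), cfg$n_canopy)
  s <- summary(fit)
  expect_lte(abs(s$mean["peak_day"] - cfg$canopy$peak_doy), 1 + 1)
  true_peak_index <- cfg$canopy$k_a *
    (cfg$canopy$tai_mean + cfg$canopy$tai_amplitude)
  # span-0.4 smoothing flattens the cosine crest slightly; 2% headroom
  expect_lt(abs(s$mean["peak_value"] - true_peak_index) / true_peak_index,
            0.02)
  # identical sensors, identical trends: SE ~ 0
  expect_lt(s$se["peak_value"], 1e-10)
  # TAI scale is index scale / k_a
  expect_equal(unname(s$tai_mean["peak_value"]),
               unname(s$mean["peak_value"]) / cfg$canopy$k_a)
})

test_that("canopy_trend methods are coherent", {
  cfg <- quiet_config(n_days = 60, start_date = "2019-06-01", seed = 2,
                      n_canopy = 2)
  sim <- simulate_deployment(cfg)
  idx <- compute_index_series(sim$loggers, sim$sensors, cfg$site)
  fit <- canopy_trend(idx, span = 0.5)
  # coef: one row per sensor, the four extrema
  cf <- coef(fit)
  expect_equal(dim(cf), c(2L, 4L))
  expect_true(all(cf[, "peak_value"] >= cf[, "trough_value"]))
  # predict default: long daily trend; with days: matrix
  tr <- predict(fit)
  expect_true(all(c("sensor_id", "day_of_year", "smoothed_index")
                  %in% names(tr)))
  pm <- predict(fit, days = c(170, 180))
  expect_equal(dim(pm), c(2L, 2L))
  expect_equal(unname(pm[1, 1]),
               unname(tr$smoothed_index[tr$sensor_id == colnames(pm)[1] &
                                          tr$day_of_year == 170]))
  # fitted + residuals reconstruct the observations
  fv <- fitted(fit)
  rs <- residuals(fit)
  expect_equal(fv[[1]] + rs[[1]], fit$fits[[1]]$y, tolerance = 1e-12)
  expect_output(print(fit), "Seasonal canopy trend")
  expect_output(print(summary(fit)), "Per-sensor extrema")
})

test_that("daily-median aggregation gives a close, faster trend", {
  cfg <- quiet_config(n_days = 90, start_date = "2019-05-15", seed = 9,
                      n_canopy = 1, n_open = 1)
  sim <- simulate_deployment(cfg)
  idx <- compute_index_series(sim$loggers, sim$sensors, cfg$site)
  fp <- canopy_trend(idx, span = 0.4)
  fd <- canopy_trend(idx, span = 0.4, aggregate = "daily-median")
  # noise-free: both modes sit on the same seasonal curve
  expect_lt(abs(coef(fp)[1, "peak_value"] - coef(fd)[1, "peak_value"]),
            0.02)
  expect_lt(abs(coef(fp)[1, "peak_day"] - coef(fd)[1, "peak_day"]), 3)
})

test_that("sensors with too few points are dropped with a warning", {
  cfg <- quiet_config(n_days = 30, seed = 4, n_canopy = 2)
  sim <- simulate_deployment(cfg)
  idx <- compute_index_series(sim$loggers, sim$sensors, cfg$site)
  # starve one sensor of data (a few points on the first morning only)
  starved <- idx[!(idx$sensor_id == "canopy_02" &
                     idx$day_of_year > 1.5), , drop = FALSE]
  expect_warning(fit <- canopy_trend(starved, span = 0.5), "canopy_02")
  expect_equal(names(fit$fits), "canopy_01")
  expect_true(all(is.na(summary(fit)$se)))
  expect_error(canopy_trend(idx[0, ]), "no retained")
})

test_that("drift_check separates stable sensors from injected decay", {
  set.seed(31)
  dates <- as.Date("2019-01-01") + 0:364
  doy <- as.POSIXlt(dates)$yday + 1
  ref <- 800 + 600 * cos(2 * pi * (doy - 172) / 365.25)
  # exact proportionality: perfect fit, flat residuals
  d0 <- drift_check(dates, 2 * ref, ref)
  expect_equal(d0$r_squared, 1, tolerance = 1e-12)
  expect_equal(d0$residual_date_r_squared, 0)
  expect_equal(d0$slope, 2, tolerance = 1e-9)
  # 30%/year linear sensitivity decay leaves a clear negative date trend
  # in the residuals, far above the stable-sensor control
  decay <- 1 - 0.3 * (seq_along(dates) - 1) / 365
  noise <- exp(rnorm(365, sd = 0.05))
  dd <- drift_check(dates, ref * decay * noise, ref)
  dc <- drift_check(dates, ref * noise, ref)
  expect_lt(dc$residual_date_r_squared, 0.05)
  expect_gt(dd$residual_date_r_squared, 10 * dc$residual_date_r_squared)
  expect_gt(dd$residual_date_r_squared, 0.2)
  expect_lt(dd$residual_date_slope, 0)
  # shuffled pairing destroys the relationship
  ds <- drift_check(dates, ref * noise, sample(ref))
  expect_lt(ds$r_squared, 0.1)
  expect_error(drift_check(dates[1:5], ref[1:5], ref[1:5]), "10")
})
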