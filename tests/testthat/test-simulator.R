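test_that("sim_config validates fields and merges nested overrides", {
  cfg <- sim_config(n_days = 10, canopy = list(tai_mean = 5))
  expect_equal(cfg$canopy$tai_mean, 5)
  expect_equal(cfg$canopy$k_a, 0.7)        # untouched sibling field
  expect_error(sim_config(bogus = 1), "unknown")
  expect_error(sim_config(canopy = list(nope = 1)), "canopy\\$nope")
  expect_error(sim_config(canopy = list(tai_mean = 1, tai_amplitude = 2)),
               "tai_mean")
  expect_error(sim_config(interval_min = 7), "1440")
})

test_that("surface light is zero at night and peaks at the solstice", {
  cfg <- quiet_config(n_days = 365)
  tms <- seq(as.POSIXct("2019-01-01 00:00", tz = "UTC"),
             by = 1800, length.out = 365 * 48)
  I_s <- simulate_surface_light(cfg, tms, noise = FALSE)
  expect_true(all(I_s >= 0))
  # solar midnight is dark
  midnights <- format(tms, "%H:%M") == "01:00"
  expect_true(all(I_s[midnights] == 0))
  # daily totals peak within 10 days of the summer solstice (day 172)
  day <- floor(day_of_year(tms))
  totals <- tapply(I_s, day, sum)
  expect_lte(abs(as.numeric(names(which.max(totals))) - 172), 10)
  # equator equinox solar noon reaches the configured peak exactly
  eq_cfg <- quiet_config()
  eq_cfg$site <- site_location(0, 0, 0)
  noon <- as.POSIXct("2019-03-20 12:07:00", tz = "UTC") + seq(-1800, 1800, 60)
  eq_light <- simulate_surface_light(eq_cfg, noon, noise = FALSE)
  expect_equal(max(eq_light) / eq_cfg$surface$peak_lux, 1,
               tolerance = 1e-4)
})

test_that("tide spans the neap and spring ranges and never goes negative", {
  cfg <- sim_config(n_days = 30)
  tms <- seq(as.POSIXct("2019-01-01 00:00", tz = "UTC"),
             by = 600, length.out = 29.5 * 144)
  z <- simulate_tide(cfg, tms)
  expect_true(all(z >= 0))
  # M2 1.55 + S2 0.95 over mean 0.9: crest-to-trough ~5 m at springs
  expect_equal(max(z), 0.9 + 1.55 + 0.95, tolerance = 0.02)
  # neap oscillation (constituents opposed) has range ~1.2 m
  # find a neap window: days 7-8 after an aligned start
  neap <- z[tms >= tms[1] + 6.5 * 86400 & tms <= tms[1] + 8 * 86400]
  expect_lt(max(neap) - min(neap), 2)
  # flat tide with amplitudes off
  cfg0 <- sim_config(tide = list(m2_amp = 0, s2_amp = 0))
  expect_equal(unique(simulate_tide(cfg0, tms[1:10])), 0.9)
})

test_that("canopy biomass cycle has the configured phase, mean and floor", {
  cfg <- sim_config()
  doy <- seq(1, 366.25, by = 1 / 48)
  tai <- simulate_canopy_biomass(cfg, doy)
  expect_true(all(tai >= 0))
  expect_equal(simulate_canopy_biomass(cfg, cfg$canopy$peak_doy),
               cfg$canopy$tai_mean + cfg$canopy$tai_amplitude)
  # annual mean equals the configured mean within 1%
  year <- doy <= 366.25
  expect_equal(mean(tai[year]) / cfg$canopy$tai_mean, 1, tolerance = 0.01)
  # constant when the amplitude is zero
  cfg0 <- sim_config(canopy = list(tai_amplitude = 0))
  expect_equal(unique(simulate_canopy_biomass(cfg0, doy)), 4.5)
})

test_that("noise-free deployments satisfy the index identity exactly", {
  cfg <- quiet_config(n_days = 15, start_date = "2019-04-01", seed = 8)
  sim <- simulate_deployment(cfg)
  # every daytime timestamp: ln(mean open / canopy) == k_a * TAI(t)
  open <- sim$loggers[sim$loggers$sensor_id == "open_01", ]
  can <- sim$loggers[sim$loggers$sensor_id == "canopy_01", ]
  day <- open$light > 0 & can$light > 0
  idx <- log(open$light[day] / can$light[day])
  expect_equal(idx, cfg$canopy$k_a * sim$truth$tai[day], tolerance = 1e-12)
})

test_that("deployments are reproducible from the seed", {
  cfg <- sim_config(n_days = 3, seed = 77)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_deployment(simulate_deployment(cfg), d1)
  write_deployment(simulate_deployment(cfg), d2)
  write_deployment(simulate_deployment(sim_config(n_days = 3, seed = 78)),
                   d3)
  for (f in c("loggers.csv", "sensors.csv", "truth.csv", "config.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_false(identical(readLines(file.path(d1, "loggers.csv")),
                         readLines(file.path(d3, "loggers.csv"))))
})

test_that("lognormal sensor noise is additive and mean-zero on the index", {
  # at a fixed bright timestamp, index - k_a*TAI = eps_o - eps_c with
  # eps ~ N(0, sigma^2): mean 0 within Monte-Carlo error
  sigma <- 0.5
  io_true <- 20000; tai <- 4; k_a <- 0.7
  ic_true <- io_true * exp(-k_a * tai)
  set.seed(123)
  n <- 1000
  io <- io_true * exp(rnorm(n, sd = sigma))
  ic <- ic_true * exp(rnorm(n, sd = sigma))
  delta <- log(io / ic) - k_a * tai
  mc_se <- sigma * sqrt(2) / sqrt(n)
  expect_lt(abs(mean(delta)), 4 * mc_se)
  expect_equal(sd(delta), sigma * sqrt(2), tolerance = 0.15)
})

test_that("sensor floor and quantization behave like a consumer lux logger", {
  cfg <- sim_config(n_days = 2, seed = 1,
                    noise = list(sigma_open = 0, sigma_canopy = 0),
                    surface = list(cloud_sigma = 0),
                    sensor = list(floor_lux = 50, quantization_lux = 10))
  sim <- simulate_deployment(cfg)
  lux <- sim$loggers$light
  expect_true(all(lux == 0 | lux >= 50))
  expect_true(all(lux %% 10 == 0))
})
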