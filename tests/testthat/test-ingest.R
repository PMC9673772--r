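test_that("logger CSV reading handles toy files, preambles and bad rows", {
  rows <- data.frame(t = c("2019-03-01T10:00:00", "2019-03-01T10:30:00",
                           "2019-03-01T11:00:00"),
                     id = "s1", lux = c(100, 200.5, 300), tc = 9.1)
  p <- write_toy_loggers(rows)
  x <- read_logger_csv(p)
  expect_equal(nrow(x), 3)
  expect_equal(x$light, c(100, 200.5, 300))
  expect_s3_class(x$timestamp, "POSIXct")
  expect_equal(attr(x, "n_skipped"), 0L)

  # commercial-export style preamble before the header
  p2 <- write_toy_loggers(rows, preamble = c("Plot Title: shore A",
                                             "Serial,12345"))
  expect_equal(nrow(read_logger_csv(p2)), 3)

  # one malformed timestamp: row dropped, warning, count of 1
  rows_bad <- rows; rows_bad$t[2] <- "not-a-time"
  p3 <- write_toy_loggers(rows_bad)
  expect_warning(x3 <- read_logger_csv(p3), "1 row")
  expect_equal(nrow(x3), 2)
  expect_equal(attr(x3, "n_skipped"), 1L)

  # missing mandatory column named in the error
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,light_lux", "2019-03-01T10:00:00,5"), p4)
  expect_error(read_logger_csv(p4), "sensor_id")
})

test_that("write/read logger CSV round-trips values exactly", {
  set.seed(42)
  n <- 50
  x <- data.frame(
    timestamp = as.POSIXct("2019-03-01 00:00", tz = "UTC") +
      seq_len(n) * 1800,
    sensor_id = rep(c("a", "b"), length.out = n),
    light = c(0, exp(runif(n - 2, 0, 11)), 12345.6789),
    temperature = round(rnorm(n, 10, 3), 3))
  x <- x[order(x$sensor_id, x$timestamp), ]
  rownames(x) <- NULL
  p <- tempfile(fileext = ".csv")
  write_logger_csv(x, p)
  y <- read_logger_csv(p)
  expect_identical(y$light, x$light)
  expect_identical(y$temperature, x$temperature)
  expect_equal(as.numeric(y$timestamp), as.numeric(x$timestamp))
})

test_that("align_to_grid snaps within tolerance and never invents values", {
  base <- as.POSIXct("2019-03-01 10:00", tz = "UTC")
  x <- data.frame(
    timestamp = c(base, base + 1800 + 60, base + 3600 + 6 * 60),
    sensor_id = "s1",
    light = c(1, 2, 3), temperature = NA_real_)
  out <- align_to_grid(x, interval_min = 30, tolerance_min = 5)
  # 1-min offset snaps; 6-min offset exceeds tolerance and is dropped
  expect_equal(attr(out, "n_dropped"), 1L)
  got <- out$light[!is.na(out$light)]
  expect_true(all(got %in% x$light))        # no invented values
  expect_equal(got, c(1, 2))
  # identical grids pass through unchanged
  x2 <- data.frame(timestamp = base + (0:5) * 1800, sensor_id = "s2",
                   light = 10 * (1:6), temperature = NA_real_)
  out2 <- align_to_grid(x2, 30)
  expect_equal(out2$light, x2$light)
  # a sensor missing one slot gets NA there, others untouched
  x3 <- rbind(x2[-3, ],
              data.frame(timestamp = base + (0:5) * 1800, sensor_id = "s3",
                         light = 1:6, temperature = NA_real_))
  out3 <- align_to_grid(x3, 30)
  s2 <- out3[out3$sensor_id == "s2", ]
  expect_true(is.na(s2$light[3]))
  expect_equal(s2$light[-3], x2$light[-3])
  expect_error(align_to_grid(x2[0, ], 30), "no records")
  expect_error(align_to_grid(x2, interval_min = 7), "divide")
})

test_that("mean open series averages available open sensors", {
  base <- as.POSIXct("2019-03-01 10:00", tz = "UTC")
  x <- data.frame(
    timestamp = rep(base + (0:2) * 1800, 3),
    sensor_id = rep(c("o1", "o2", "o3"), each = 3),
    light = c(100, 100, 100, 200, 200, NA, 300, NA, NA),
    temperature = NA_real_)
  meta <- toy_meta(c("o1", "o2", "o3"), "open")
  io <- mean_open_series(x, meta)
  expect_equal(io$I_o, c(200, 150, 100))
  expect_equal(io$n_open, c(3L, 2L, 1L))
  # single sensor: identical to that sensor
  io1 <- mean_open_series(x[x$sensor_id == "o1", ], toy_meta("o1", "open"))
  expect_equal(io1$I_o, c(100, 100, 100))
  expect_error(mean_open_series(x, toy_meta("o1", "canopy")), "open")
  # commutes with common scaling
  xs <- x; xs$light <- xs$light * 3.5
  expect_equal(mean_open_series(xs, meta)$I_o, io$I_o * 3.5)
})

test_that("mask windows are half-open, counted and idempotent", {
  base <- as.POSIXct("2019-03-01 10:00", tz = "UTC")
  x <- data.frame(timestamp = base + (0:5) * 1800, sensor_id = "s1",
                  light = 1:6, temperature = NA_real_)
  # empty list: unchanged
  out0 <- apply_mask_windows(x, NULL)
  expect_equal(out0$light, x$light)
  expect_equal(attr(out0, "n_masked"), 0L)
  # [t2, t4): exactly slots 3 and 4 (0-based t2, t3)
  w <- data.frame(sensor_id = "s1", start = base + 2 * 1800,
                  end = base + 4 * 1800, reason = "fouling")
  out <- apply_mask_windows(x, w)
  expect_identical(is.na(out$light), c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "n_masked"), 2L)
  # idempotent; re-masking counts nothing new
  out2 <- apply_mask_windows(out, w)
  expect_identical(out2$light, out$light)
  expect_equal(attr(out2, "n_masked"), 0L)
  # whole-record window via the wildcard sensor
  wall <- data.frame(sensor_id = "*", start = base - 1,
                     end = base + 1e6, reason = "all")
  expect_true(all(is.na(apply_mask_windows(x, wall)$light)))
  # other sensors untouched
  w2 <- data.frame(sensor_id = "other", start = base - 1,
                   end = base + 1e6, reason = "na")
  expect_equal(apply_mask_windows(x, w2)$light, x$light)
})

test_that("coverage report counts present slots per sensor", {
  base <- as.POSIXct("2019-03-01 10:00", tz = "UTC")
  x <- data.frame(timestamp = rep(base + (0:3) * 1800, 2),
                  sensor_id = rep(c("a", "b"), each = 4),
                  light = c(1, 2, 3, 4, 1, NA, NA, 4),
                  temperature = NA_real_)
  cv <- coverage_report(x)
  expect_equal(cv$coverage[cv$sensor_id == "a"], 1)
  expect_equal(cv$coverage[cv$sensor_id == "b"], 0.5)
})
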