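#' Fit the seasonal canopy trend to an attenuation-index series
#'
#' The central model fit: one LOESS smooth of the filtered attenuation
#' index `ln(I_o/I_c)` against fractional day of year per under-canopy
#' sensor, evaluated on a uniform daily grid, with seasonal extrema
#' (peak/trough value and day) per sensor and cross-sensor mean/SE. With a
#' canopy attenuation coefficient `k_a`, extrema are also reported on the
#' thallus-area-index scale (`index / k_a`).
#'
#' Smoothing defaults to the raw half-hourly retained points (`aggregate =
#' "points"`); `"daily-median"` pre-aggregates each sensor to daily medians
#' first, which is faster and damps within-day weather noise at the cost
#' of within-day information. The span is a fraction of present points.
#' Sensors with fewer usable points than the LOESS minimum are dropped
#' with a warning.
#'
#' @param index data.frame with columns `sensor_id`, `day_of_year`,
#'   `index` (typically from [compute_index_series()]; rows with `status`
#'   are filtered to `"retained"` when that column is present).
#' @param span LOESS span in `(0, 1]`; default 0.4, which tracks the
#'   gradual build-up and decline of fucoid biomass over a year without
#'   chasing weather.
#' @param degree local polynomial degree (1 or 2).
#' @param robust_iter bisquare robustness iterations for the LOESS fit.
#' @param aggregate `"points"` or `"daily-median"`.
#' @param k_a optional canopy attenuation coefficient for the TAI scale.
#' @param grid_by spacing of the daily evaluation grid, days.
#' @return An object of class `"canopy_trend"`: see
#'   [summary.canopy_trend()], [coef.canopy_trend()],
#'   [predict.canopy_trend()], [plot.canopy_trend()].
#' @export
#' @examples
#' sim <- simulate_deployment(sim_config(n_days = 120, seed = 1))
#' idx <- compute_index_series(sim$loggers, sim$sensors, sim$config$site)
#' fit <- canopy_trend(idx, k_a = 0.7)
#' summary(fit)
canopy_trend <- function(index, span = 0.4, degree = 1, robust_iter = 0,
                         aggregate = c("points", "daily-median"),
                         k_a = NULL, grid_by = 1) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(index),
            all(c("sensor_id", "day_of_year", "index") %in% names(index)))
  if ("status" %in% names(index))
    index <- index[index$status == "retained", , drop = FALSE]
  index <- index[!is.na(index$index), , drop = FALSE]
  if (nrow(index) == 0L) stop("no retained index points", call. = FALSE)
  sensors <- sort(unique(index$sensor_id))
  min_pts <- max(degree + 2, 10)
  fits <- list()
  dropped <- character(0)
  for (id in sensors) {
    d <- index[index$sensor_id == id, , drop = FALSE]
    x <- d$day_of_year
    y <- d$index
    if (aggregate == "daily-median") {
      day <- floor(x - 1e-9)
      y <- as.numeric(tapply(y, day, stats::median))
      x <- sort(unique(day)) + 0.5
    }
    if (length(x) < min_pts) {
      warning("sensor ", id, " has too few points (", length(x),
              ") and was dropped from the trend", call. = FALSE)
      dropped <- c(dropped, id)
      next
    }
    lo <- ceiling(min(x)); hi <- floor(max(x))
    grid <- if (lo > hi) seq(min(x), max(x), length.out = 25)
            else seq(lo, hi, by = grid_by)
    sm <- loess_smooth(x, y, span = span, degree = degree, eval = grid,
                       robust_iter = robust_iter)
    fits[[id]] <- list(x = x, y = y, grid = grid, smoothed = sm,
                       extrema = extract_extrema(grid, sm))
  }
  if (length(fits) == 0L)
    stop("no sensor had enough points for a trend fit", call. = FALSE)
  extrema <- do.call(rbind, lapply(fits, `[[`, "extrema"))
  structure(list(fits = fits, extrema = extrema,
                 summary = summarize_sensors(extrema),
                 span = span, degree = degree, robust_iter = robust_iter,
                 aggregate = aggregate, k_a = k_a, grid_by = grid_by,
                 dropped = dropped, call = match.call()),
            class = "canopy_trend")
}

#' @export
print.canopy_trend <- function(x, ...) {
  cat(sprintf(
    "Seasonal canopy trend: LOESS span %.2f, degree %d, %s mode\n",
    x$span, x$degree, x$aggregate))
  cat(sprintf("  %d sensor(s), %d points total\n", length(x$fits),
              sum(vapply(x$fits, function(f) length(f$x), 1L))))
  s <- x$summary
  cat(sprintf("  peak index  %.3f (SE %s) on day %.1f (SE %s)\n",
              s$mean["peak_value"], fmt_se(s$se["peak_value"]),
              s$mean["peak_day"], fmt_se(s$se["peak_day"])))
  cat(sprintf("  trough index %.3f (SE %s) on day %.1f (SE %s)\n",
              s$mean["trough_value"], fmt_se(s$se["trough_value"]),
              s$mean["trough_day"], fmt_se(s$se["trough_day"])))
  if (!is.null(x$k_a))
    cat(sprintf("  TAI scale (k_a = %.2f): peak %.2f, trough %.2f\n",
                x$k_a, s$mean["peak_value"] / x$k_a,
                s$mean["trough_value"] / x$k_a))
  invisible(x)
}

fmt_se <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' Summarise a canopy trend fit
#'
#' @param object a [canopy_trend()] fit.
#' @param ... unused.
#' @return A list of class `"summary.canopy_trend"` with the per-sensor
#'   extrema, cross-sensor mean/SE on the index scale and, when `k_a` was
#'   supplied, on the thallus-area-index scale.
#' @export
summary.canopy_trend <- function(object, ...) {
  s <- object$summary
  out <- list(extrema = object$extrema, n_sensors = s$n_sensors,
              mean = s$mean, se = s$se, span = object$span,
              degree = object$degree, k_a = object$k_a,
              dropped = object$dropped)
  if (!is.null(object$k_a)) {
    sc <- c(peak_value = 1 / object$k_a, peak_day = 1,
            trough_value = 1 / object$k_a, trough_day = 1)
    out$tai_mean <- s$mean * sc
    out$tai_se <- s$se * sc
  }
  class(out) <- "summary.canopy_trend"
  out
}

#' @export
print.summary.canopy_trend <- function(x, ...) {
  cat(sprintf("Seasonal canopy trend (LOESS span %.2f, degree %d)\n",
              x$span, x$degree))
  cat("Per-sensor extrema:\n")
  print(round(x$extrema, 3))
  cat(sprintf("\nAcross %d sensor(s) (mean, SE = sd/sqrt(n)):\n",
              x$n_sensors))
  tab <- rbind(mean = x$mean, se = x$se)
  print(round(tab, 3))
  if (!is.null(x$k_a)) {
    cat(sprintf("\nThallus area index scale (k_a = %.2f):\n", x$k_a))
    print(round(rbind(mean = x$tai_mean, se = x$tai_se), 3))
  }
  if (length(x$dropped))
    cat("\nDropped sensors:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.canopy_trend <- function(object, ...) object$extrema

#' Evaluate a fitted canopy trend
#'
#' Evaluates each sensor's LOESS smooth at new day-of-year values (by
#' refitting the stored local regressions at the requested points).
#'
#' @param object a [canopy_trend()] fit.
#' @param days numeric day-of-year values; default each sensor's stored
#'   daily grid.
#' @param ... unused.
#' @return With `days` supplied: a matrix (days x sensors). Otherwise a
#'   long data.frame `sensor_id`, `day_of_year`, `smoothed_index`.
#' @export
predict.canopy_trend <- function(object, days = NULL, ...) {
  if (is.null(days)) {
    out <- do.call(rbind, lapply(names(object$fits), function(id) {
      f <- object$fits[[id]]
      data.frame(sensor_id = id, day_of_year = f$grid,
                 smoothed_index = f$smoothed, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  vapply(object$fits, function(f)
    loess_smooth(f$x, f$y, span = object$span, degree = object$degree,
                 eval = days, robust_iter = object$robust_iter),
    numeric(length(days)))
}

#' @export
fitted.canopy_trend <- function(object, ...) {
  lapply(object$fits, function(f)
    loess_smooth(f$x, f$y, span = object$span, degree = object$degree,
                 eval = f$x, robust_iter = object$robust_iter))
}

#' @export
residuals.canopy_trend <- function(object, ...) {
  fv <- fitted(object)
  lapply(names(fv), function(id) object$fits[[id]]$y - fv[[id]])
}

#' Plot a canopy trend fit
#'
#' One panel per sensor: retained index points with the LOESS trend line.
#'
#' @param x a [canopy_trend()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.canopy_trend <- function(x, ...) {
  ids <- names(x$fits)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (id in ids) {
    f <- x$fits[[id]]
    graphics::plot(f$x, f$y, pch = ".", col = "grey40",
                   xlab = "day of year", ylab = "ln(Io/Ic)",
                   main = id, ...)
    graphics::lines(f$grid, f$smoothed, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Sensor drift diagnostic against a reference radiation series
#'
#' Regresses daily mean light from the exposed (open-rock) loggers on an
#' independent daily reference series (e.g. global radiation from a nearby
#' met station), then regresses the residuals on date. A sensitivity drift
#' shows up as date structure in the residuals; a residual-vs-date r^2
#' near zero indicates stable sensors.
#'
#' @param date `Date` vector of the paired days.
#' @param logger daily mean exposed-logger light.
#' @param reference daily reference radiation (any consistent unit).
#' @return Object of class `"drift_report"`: regression `slope`,
#'   `intercept`, `r_squared`, plus `residual_date_r_squared` and
#'   `residual_date_slope`.
#' @export
drift_check <- function(date, logger, reference) {
  ok <- !is.na(logger) & !is.na(reference) & !is.na(date)
  if (sum(ok) < 10)
    stop("drift_check needs at least 10 paired days", call. = FALSE)
  date <- as.Date(date)[ok]; logger <- logger[ok]
  reference <- reference[ok]
  fit <- stats::lm(logger ~ reference)
  # r^2 computed directly (summary.lm warns on numerically exact fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((logger - mean(logger))^2)
  dnum <- as.numeric(date)
  res <- stats::residuals(fit)
  if (stats::var(res) <= 1e-20 * stats::var(logger)) {
    # numerically exact fit: no residual structure to regress
    rd_slope <- 0
    rd_r2 <- 0
  } else {
    rfit <- stats::lm(res ~ dnum)
    rd_slope <- unname(stats::coef(rfit)[2])
    rd_r2 <- summary(rfit)$r.squared
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residual_date_slope = rd_slope,
                 residual_date_r_squared = rd_r2,
                 n_days = sum(ok)),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat("Sensor drift diagnostic\n")
  cat(sprintf("  logger ~ reference: slope %.4g, intercept %.4g, r2 %.3f (n = %d days)\n",
              x$slope, x$intercept, x$r_squared, x$n_days))
  cat(sprintf("  residuals ~ date:   r2 %.4f%s\n",
              x$residual_date_r_squared,
              if (x$residual_date_r_squared < 0.05)
                " (no evidence of drift)" else " (possible drift)"))
  invisible(x)
}
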