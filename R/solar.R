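#' Site location for solar geometry
#'
#' @param latitude degrees north, in `[-90, 90]`.
#' @param longitude degrees east, in `[-180, 180]` (west negative).
#' @param utc_offset hours the logger clock is ahead of UTC. Timestamps in
#'   this package are naive clock times; the offset plus the longitude give
#'   the clock-to-solar-time correction.
#' @return An object of class `"site_location"`.
#' @export
#' @examples
#' furbo <- site_location(53.246, -9.221)
site_location <- function(latitude, longitude, utc_offset = 0) {
  stopifnot(is.numeric(latitude), length(latitude) == 1L,
            latitude >= -90, latitude <= 90,
            is.numeric(longitude), length(longitude) == 1L,
            longitude >= -180, longitude <= 180,
            is.numeric(utc_offset), length(utc_offset) == 1L,
            is.finite(utc_offset))
  structure(list(latitude = latitude, longitude = longitude,
                 utc_offset = utc_offset),
            class = "site_location")
}

#' @export
print.site_location <- function(x, ...) {
  cat(sprintf("Site: %.4f%sN, %.4f%sE (UTC%+g)\n", x$latitude, "°",
              x$longitude, "°", x$utc_offset))
  invisible(x)
}

# Fourier-series solar ephemeris (fractional-year expansion): equation of
# time in minutes and solar declination in radians.
solar_ephemeris <- function(doy, hour = 12) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  list(eqtime_min = eqtime, decl_rad = decl)
}

#' Dawn, dusk and daylength for a calendar day
#'
#' Computes the daylight window from solar declination and the hour angle
#' of the zero-elevation crossing, with the equation-of-time and longitude
#' correction so that the returned instants are on the logger's clock. The
#' default convention is the crossing of the sun's centre with no
#' atmospheric refraction; set `refraction = TRUE` for the standard
#' rise/set zenith of 90.833 degrees (upper limb plus refraction), which is
#' what most published sunrise tables use. Polar day returns a 24 h window
#' and polar night a zero-length window at solar noon.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @param site a [site_location()].
#' @param refraction logical; use the 90.833 degree rise/set zenith.
#' @return A data.frame with columns `date`, `dawn`, `dusk` (POSIXct, clock
#'   time stored as UTC), and `daylength_h`.
#' @export
#' @examples
#' daylight_window(as.Date("2019-06-21"), site_location(53.246, -9.221))
daylight_window <- function(date, site, refraction = FALSE) {
  stopifnot(inherits(site, "site_location"))
  date <- as.Date(date)
  doy <- as.POSIXlt(date)$yday + 1
  eph <- solar_ephemeris(doy)
  phi <- site$latitude * pi / 180
  zen <- if (refraction) 90.833 * pi / 180 else pi / 2
  cos_ha <- (cos(zen) - sin(phi) * sin(eph$decl_rad)) /
    (cos(phi) * cos(eph$decl_rad))
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  # minutes on the local clock
  noon_min <- 720 - 4 * site$longitude - eph$eqtime_min + 60 * site$utc_offset
  ha_deg <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi
  daylength <- 2 * ha_deg / 15
  dawn_min <- noon_min - 4 * ha_deg
  dusk_min <- noon_min + 4 * ha_deg
  # polar cases: cos_ha >= 1 no sunrise, <= -1 no sunset
  night <- cos_ha >= 1
  day <- cos_ha <= -1
  daylength[night] <- 0
  dawn_min[night] <- dusk_min[night] <- noon_min[night]
  daylength[day] <- 24
  dawn_min[day] <- noon_min[day] - 720
  dusk_min[day] <- noon_min[day] + 720
  data.frame(date = date,
             dawn = midnight + dawn_min * 60,
             dusk = midnight + dusk_min * 60,
             daylength_h = daylength)
}

#' Position of a timestamp within its daylight window
#'
#' Maps clock instants to the fraction of the day's daylight elapsed, with
#' dawn scaled to 0 and dusk to 1. Values outside `[0, 1]` (and `NA` on
#' polar-night days) indicate night.
#'
#' @param time POSIXct clock times (stored as UTC).
#' @param window either a [site_location()] (the window for each
#'   timestamp's date is computed internally) or a data.frame from
#'   [daylight_window()] covering the dates of `time`.
#' @param refraction passed to [daylight_window()] when `window` is a site.
#' @return Numeric vector of daylight fractions.
#' @export
daylight_fraction <- function(time, window, refraction = FALSE) {
  if (inherits(window, "site_location")) {
    dates <- sort(unique(as.Date(time, tz = "UTC")))
    window <- daylight_window(dates, window, refraction = refraction)
  }
  i <- match(as.Date(time, tz = "UTC"), window$date)
  if (anyNA(i))
    stop("daylight window table does not cover all dates", call. = FALSE)
  len_s <- window$daylength_h[i] * 3600
  frac <- as.numeric(time) - as.numeric(window$dawn[i])
  ifelse(len_s > 0, frac / len_s, NA_real_)
}

#' Solar elevation angle
#'
#' Elevation of the sun's centre above the horizon, in degrees, for clock
#' timestamps at a site. Used by the light-climate simulator and available
#' for diagnostics.
#'
#' @inheritParams daylight_fraction
#' @param site a [site_location()].
#' @return Elevation in degrees (negative below the horizon).
#' @export
solar_elevation <- function(time, site) {
  stopifnot(inherits(site, "site_location"))
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  min_of_day <- lt$hour * 60 + lt$min + lt$sec / 60
  eph <- solar_ephemeris(doy, hour = min_of_day / 60)
  tst <- min_of_day + eph$eqtime_min + 4 * site$longitude -
    60 * site$utc_offset
  ha <- (tst / 4 - 180) * pi / 180
  phi <- site$latitude * pi / 180
  sin_el <- sin(phi) * sin(eph$decl_rad) +
    cos(phi) * cos(eph$decl_rad) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) * 180 / pi
}
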