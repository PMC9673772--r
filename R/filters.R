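#' Crepuscular trimming of an index series
#'
#' Attenuation-index values near dawn and dusk are unreliable: the index
#' shows a systematic dip in the first and last portion of daylight
#' (plausibly reduced sensor sensitivity at low light, or a shift in the
#' diffuse/direct balance under the canopy). This filter replaces index
#' values whose daylight fraction lies in the first or last `fraction` of
#' daylight — and all night values — with `NA`.
#'
#' @param index numeric index values.
#' @param frac_daylight daylight fraction of each value, from
#'   [daylight_fraction()] (`NA` or outside `[0, 1]` means night).
#' @param fraction trimmed fraction at each end, in `[0, 0.5)`; default 0.1
#'   (drop the first and last tenth of daylight).
#' @return `index` with trimmed values set to `NA`. Idempotent.
#' @export
crepuscular_filter <- function(index, frac_daylight, fraction = 0.1) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (is.na(fraction) || fraction < 0 || fraction >= 0.5)
    stop("'fraction' must be in [0, 0.5)", call. = FALSE)
  stopifnot(length(index) == length(frac_daylight))
  drop <- is.na(frac_daylight) | frac_daylight < fraction |
    frac_daylight > 1 - fraction
  index[drop] <- NA_real_
  index
}

#' Fractional day of year
#'
#' Converts clock timestamps to fractional days since the start of
#' `origin_year`, with 00:00 on 1 January mapping to day 1.0 (so noon on
#' 12 June of a non-leap year is day 163.5, and 31 December ends at day
#' 366.0). Deployments crossing a year boundary continue past 365/366
#' rather than wrapping, so a single monotone axis covers the whole
#' record.
#'
#' @param time POSIXct clock timestamps (stored as UTC).
#' @param origin_year calendar year anchoring day 1; default the year of
#'   the earliest timestamp.
#' @return Numeric fractional day of year.
#' @export
#' @examples
#' day_of_year(as.POSIXct("2019-06-12 12:00:00", tz = "UTC"))  # 163.5
day_of_year <- function(time, origin_year = NULL) {
  if (length(time) == 0L) return(numeric(0))
  if (is.null(origin_year))
    origin_year <- as.POSIXlt(min(time, na.rm = TRUE), tz = "UTC")$year + 1900
  origin <- as.POSIXct(paste0(origin_year, "-01-01 00:00:00"), tz = "UTC")
  as.numeric(difftime(time, origin, units = "days")) + 1
}
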