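#' Compute filtered attenuation-index series per canopy sensor
#'
#' Full journey from raw logger records to analysis-ready index points:
#' align to a common grid, apply fouling masks, build the mean open-rock
#' reference `I_o`, take `ln(I_o/I_c)` for each under-canopy sensor, and
#' apply the night/zero and crepuscular filters. Each record carries a
#' status so the filters are auditable; counts satisfy
#' `retained + night_zero + crepuscular + masked == total` per sensor.
#'
#' @param loggers long logger data.frame ([read_logger_csv()] schema).
#' @param meta sensor metadata with `sensor_id` and `role`.
#' @param site a [site_location()].
#' @param mask_windows optional data.frame of fouling windows
#'   ([read_mask_windows()]).
#' @param light_threshold zero-light threshold passed to
#'   [attenuation_index()] (default 0: strict positivity on both sensors).
#' @param crepuscular_fraction daylight fraction trimmed at each end
#'   (default 0.1).
#' @param interval_min,tolerance_min grid parameters for
#'   [align_to_grid()].
#' @param refraction dawn/dusk convention, see [daylight_window()].
#' @param origin_year anchor year for [day_of_year()]; default the first
#'   record's year.
#' @return Data.frame with one row per (canopy sensor, grid timestamp):
#'   `sensor_id`, `timestamp`, `day_of_year`, `daylight_fraction`, `I_o`,
#'   `I_c`, `index` (`NA` unless retained) and `status` (one of
#'   `retained`, `night_zero`, `crepuscular`, `masked`). Attribute
#'   `counts` tabulates statuses per sensor.
#' @export
compute_index_series <- function(loggers, meta, site,
                                 mask_windows = NULL,
                                 light_threshold = 0,
                                 crepuscular_fraction = 0.1,
                                 interval_min = 30, tolerance_min = 5,
                                 refraction = FALSE,
                                 origin_year = NULL) {
  stopifnot(inherits(site, "site_location"))
  canopy_ids <- meta$sensor_id[meta$role == "canopy"]
  if (length(canopy_ids) == 0L)
    stop("no canopy-role sensors in metadata", call. = FALSE)
  aligned <- align_to_grid(loggers, interval_min, tolerance_min)
  aligned <- apply_mask_windows(aligned, mask_windows)
  masked_rows <- attr(aligned, "masked_rows")
  open <- mean_open_series(aligned, meta)
  grid <- open$timestamp
  if (is.null(origin_year))
    origin_year <- as.POSIXlt(min(grid), tz = "UTC")$year + 1900
  doy <- day_of_year(grid, origin_year)
  dfrac <- daylight_fraction(grid, site, refraction = refraction)

  masked_flag <- rep(FALSE, nrow(aligned))
  masked_flag[masked_rows] <- TRUE

  res <- vector("list", length(canopy_ids))
  for (k in seq_along(canopy_ids)) {
    id <- canopy_ids[k]
    rows <- aligned$sensor_id == id
    ic <- aligned$light[rows][match(grid, aligned$timestamp[rows])]
    is_masked <- masked_flag[rows][match(grid, aligned$timestamp[rows])]
    is_masked[is.na(is_masked)] <- FALSE
    valid <- night_zero_mask(open$I_o, ic, light_threshold)
    idx <- rep(NA_real_, length(grid))
    idx[valid] <- log(open$I_o[valid] / ic[valid])
    idx_f <- crepuscular_filter(idx, dfrac, crepuscular_fraction)
    status <- rep("retained", length(grid))
    status[valid & is.na(idx_f)] <- "crepuscular"
    status[!valid] <- "night_zero"
    status[is_masked] <- "masked"
    idx_f[status != "retained"] <- NA_real_
    res[[k]] <- data.frame(sensor_id = id, timestamp = grid,
                           day_of_year = doy, daylight_fraction = dfrac,
                           I_o = open$I_o, I_c = ic, index = idx_f,
                           status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "counts") <- table(out$sensor_id, out$status)
  attr(out, "site") <- site
  attr(out, "params") <- list(light_threshold = light_threshold,
                              crepuscular_fraction = crepuscular_fraction,
                              interval_min = interval_min,
                              origin_year = origin_year)
  out
}

#' Write / read an index-series CSV
#'
#' @param x data.frame from [compute_index_series()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_index_csv <- function(x, path) {
  df <- x
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (col in c("day_of_year", "daylight_fraction", "I_o", "I_c", "index"))
    df[[col]] <- num_chr(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_index_csv
#' @export
read_index_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- parse_timestamps(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  df
}
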