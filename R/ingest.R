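#' Read a long-format light-logger CSV export
#'
#' Reads timestamped light and temperature records for one or more sensors
#' from a long-format CSV with (at least) a timestamp, a sensor id and a
#' light column. Commercial logger exports often carry a free-text
#' preamble before the header line ("Plot title: ...", serial numbers and
#' so on); the reader scans for the first line containing the configured
#' timestamp column name and treats it as the header. Rows whose timestamp
#' fails to parse are skipped with a warning; negative light readings are
#' set to `NA` with a warning.
#'
#' @param path CSV file path.
#' @param cols named character vector mapping canonical names to file
#'   column names; must name `timestamp`, `sensor_id` and `light`;
#'   `temperature` is optional (filled with `NA` when absent).
#' @param time_formats candidate `strptime` formats tried in order.
#' @param max_preamble maximum number of lines scanned for the header.
#' @return A data.frame with columns `timestamp` (POSIXct, clock time
#'   stored as UTC), `sensor_id`, `light`, `temperature`, sorted by sensor
#'   then time, with attribute `n_skipped` (unparseable rows dropped).
#' @export
read_logger_csv <- function(path,
                            cols = c(timestamp = "timestamp",
                                     sensor_id = "sensor_id",
                                     light = "light_lux",
                                     temperature = "temp_c"),
                            time_formats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S",
                                             "%Y-%m-%d %H:%M",
                                             "%d/%m/%Y %H:%M"),
                            max_preamble = 50) {
  need <- c("timestamp", "sensor_id", "light")
  if (!all(need %in% names(cols)))
    stop("'cols' must map: ", paste(setdiff(need, names(cols)),
                                    collapse = ", "), call. = FALSE)
  head_lines <- readLines(path, n = max_preamble)
  hdr <- grep(cols[["timestamp"]], head_lines, fixed = TRUE)[1]
  if (is.na(hdr))
    stop("no header line containing column '", cols[["timestamp"]],
         "' found in ", path, call. = FALSE)
  raw <- utils::read.csv(path, skip = hdr - 1L, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (canon in need) {
    if (!cols[[canon]] %in% names(raw))
      stop("missing mandatory column '", cols[[canon]], "' in ", path,
           call. = FALSE)
  }
  ts <- parse_timestamps(as.character(raw[[cols[["timestamp"]]]]),
                         time_formats)
  bad <- is.na(ts)
  if (any(bad))
    warning(sum(bad), " row(s) with unparseable timestamps skipped",
            call. = FALSE)
  temp <- if ("temperature" %in% names(cols) &&
              cols[["temperature"]] %in% names(raw))
    as.numeric(raw[[cols[["temperature"]]]]) else NA_real_
  out <- data.frame(timestamp = ts,
                    sensor_id = as.character(raw[[cols[["sensor_id"]]]]),
                    light = as.numeric(raw[[cols[["light"]]]]),
                    temperature = temp,
                    stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  neg <- !is.na(out$light) & out$light < 0
  if (any(neg)) {
    warning(sum(neg), " negative light reading(s) set to NA", call. = FALSE)
    out$light[neg] <- NA_real_
  }
  out <- out[order(out$sensor_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

parse_timestamps <- function(x, formats) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  todo <- rep(TRUE, length(x))
  for (f in formats) {
    if (!any(todo)) break
    p <- as.POSIXct(strptime(x[todo], format = f, tz = "UTC"))
    hit <- !is.na(p)
    out[which(todo)[hit]] <- p[hit]
    todo[todo] <- !hit
  }
  out
}

#' Write a logger table back to the canonical CSV schema
#'
#' ISO-8601 timestamps, `.` decimal separator regardless of locale, full
#' double precision so that `read_logger_csv(write_logger_csv(x))` is an
#' exact round trip.
#'
#' @param x data.frame as returned by [read_logger_csv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(x, path) {
  df <- data.frame(timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                   sensor_id = x$sensor_id,
                   light_lux = num_chr(x$light),
                   temp_c = num_chr(x$temperature),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal representation that round-trips a double
num_chr <- function(x) {
  out <- rep("NA", length(x))
  p <- which(!is.na(x))
  if (length(p)) {
    full <- sprintf("%.17g", x[p])
    short <- sprintf("%.15g", x[p])
    keep_short <- as.numeric(short) == x[p]
    out[p] <- ifelse(keep_short, short, full)
  }
  out
}

#' Read sensor metadata
#'
#' @param path CSV with columns `sensor_id`, `role` (each `canopy` or
#'   `open`), and optionally `patch_id` and `height_above_datum_m`.
#' @return Validated data.frame.
#' @export
read_sensor_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sensor_id", "role"))
    if (!col %in% names(meta))
      stop("missing mandatory column '", col, "' in ", path, call. = FALSE)
  if (anyDuplicated(meta$sensor_id))
    stop("duplicate sensor_id in ", path, call. = FALSE)
  if (!all(meta$role %in% c("canopy", "open")))
    stop("role must be 'canopy' or 'open'", call. = FALSE)
  meta
}

#' Read fouling/maintenance mask windows
#'
#' @param path CSV with columns `sensor_id` (`*` matches every sensor),
#'   `start`, `end` (ISO-8601), `reason`.
#' @return Data.frame with POSIXct `start`/`end`; `start < end` enforced.
#' @export
read_mask_windows <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sensor_id", "start", "end"))
    if (!col %in% names(w))
      stop("missing mandatory column '", col, "' in ", path, call. = FALSE)
  w$start <- parse_timestamps(w$start,
                              c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                "%Y-%m-%d"))
  w$end <- parse_timestamps(w$end,
                            c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d"))
  if (anyNA(w$start) || anyNA(w$end))
    stop("unparseable mask window timestamps in ", path, call. = FALSE)
  if (any(w$start >= w$end))
    stop("mask windows must satisfy start < end", call. = FALSE)
  if (is.null(w$reason)) w$reason <- ""
  w
}

#' Align logger series onto a common time grid
#'
#' Snaps each record to the nearest point of a shared grid (anchored at
#' midnight, spacing `interval_min`) and re-indexes every sensor onto the
#' full grid from the earliest to the latest snapped record across all
#' sensors. Slots a sensor did not report become `NA`; light values are
#' never interpolated or otherwise invented. Records farther than
#' `tolerance_min` from any grid point are dropped (counted in attribute
#' `n_dropped`); when two records snap to the same slot the nearer one
#' wins.
#'
#' @param x long logger data.frame ([read_logger_csv()] schema).
#' @param interval_min grid spacing in minutes; must divide 24 h evenly.
#' @param tolerance_min maximum snap distance in minutes.
#' @return Long data.frame on the common grid with attribute `n_dropped`.
#' @export
align_to_grid <- function(x, interval_min = 30, tolerance_min = 5) {
  if (nrow(x) == 0L) stop("no records to align", call. = FALSE)
  if (1440 %% interval_min != 0)
    stop("'interval_min' must divide 24 h evenly", call. = FALSE)
  step <- interval_min * 60
  tnum <- as.numeric(x$timestamp)
  snapped <- round(tnum / step) * step
  dist <- abs(tnum - snapped)
  keep <- dist <= tolerance_min * 60
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  snapped <- snapped[keep]
  dist <- dist[keep]
  # nearest record wins within a slot
  ord <- order(x$sensor_id, snapped, dist)
  x <- x[ord, , drop = FALSE]
  snapped <- snapped[ord]
  dup <- duplicated(data.frame(x$sensor_id, snapped))
  x <- x[!dup, , drop = FALSE]
  snapped <- snapped[!dup]
  grid <- seq(min(snapped), max(snapped), by = step)
  sensors <- sort(unique(x$sensor_id))
  full <- data.frame(
    timestamp = as.POSIXct(rep(grid, length(sensors)),
                           origin = "1970-01-01", tz = "UTC"),
    sensor_id = rep(sensors, each = length(grid)),
    stringsAsFactors = FALSE)
  key_full <- paste(full$sensor_id, rep(grid, length(sensors)))
  key_x <- paste(x$sensor_id, snapped)
  i <- match(key_full, key_x)
  full$light <- x$light[i]
  full$temperature <- x$temperature[i]
  attr(full, "n_dropped") <- n_dropped
  full
}

#' Mean open-rock reference series
#'
#' The open-rock reference `I_o` is the per-timestamp arithmetic mean over
#' all open-role sensors with a present value (sensors fail and foul in
#' the field; the mean of whatever is available is the contract, with no
#' imputation). Timestamps where no open sensor reports are `NA`.
#'
#' @param x aligned long logger data.frame.
#' @param meta sensor metadata with `sensor_id` and `role`.
#' @return Data.frame with `timestamp`, `I_o`, and `n_open` (contributing
#'   sensors per timestamp).
#' @export
mean_open_series <- function(x, meta) {
  open_ids <- meta$sensor_id[meta$role == "open"]
  if (length(open_ids) == 0L)
    stop("no open-role sensors in metadata", call. = FALSE)
  xo <- x[x$sensor_id %in% open_ids, , drop = FALSE]
  if (nrow(xo) == 0L)
    stop("no records from open-role sensors", call. = FALSE)
  tms <- sort(unique(xo$timestamp))
  f <- factor(as.numeric(xo$timestamp), levels = as.numeric(tms))
  sums <- tapply(ifelse(is.na(xo$light), 0, xo$light), f, sum)
  ns <- tapply(!is.na(xo$light), f, sum)
  io <- ifelse(ns > 0, sums / ns, NA_real_)
  data.frame(timestamp = tms, I_o = as.numeric(io),
             n_open = as.integer(ns))
}

#' Mask light records inside declared windows
#'
#' Sets `light` to `NA` for records falling in half-open windows
#' `[start, end)` that match the record's sensor (windows with sensor_id
#' `*` match all sensors). Half-open windows compose without
#' double-masking at shared boundaries; the operation is idempotent.
#'
#' @param x long logger data.frame.
#' @param windows data.frame from [read_mask_windows()] (or `NULL`).
#' @return `x` with masked light values and attribute `n_masked` (points
#'   newly set to `NA`).
#' @export
apply_mask_windows <- function(x, windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    attr(x, "n_masked") <- 0L
    return(x)
  }
  hit <- rep(FALSE, nrow(x))
  for (j in seq_len(nrow(windows))) {
    m <- (windows$sensor_id[j] == "*" |
            x$sensor_id == windows$sensor_id[j]) &
      x$timestamp >= windows$start[j] & x$timestamp < windows$end[j]
    hit <- hit | m
  }
  n_masked <- sum(hit & !is.na(x$light))
  x$light[hit] <- NA_real_
  attr(x, "n_masked") <- n_masked
  attr(x, "masked_rows") <- which(hit)
  x
}

#' Per-sensor data coverage
#'
#' Fraction of aligned grid slots with a present light value, per sensor.
#' A quick health report for deployments with sensor failures.
#'
#' @param x aligned long logger data.frame.
#' @return Data.frame with `sensor_id`, `n_slots`, `n_present`, `coverage`.
#' @export
coverage_report <- function(x) {
  sensors <- sort(unique(x$sensor_id))
  n_slots <- as.integer(table(factor(x$sensor_id, levels = sensors)))
  n_present <- as.integer(tapply(!is.na(x$light),
                                 factor(x$sensor_id, levels = sensors),
                                 sum))
  data.frame(sensor_id = sensors, n_slots = n_slots,
             n_present = n_present, coverage = n_present / n_slots)
}
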