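#' Pipeline step: simulate a deployment to disk
#'
#' Thin orchestration over [simulate_deployment()] / [write_deployment()]
#' plus a provenance record, for use from scripts and the command line.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config = sim_config(), out_dir) {
  sim <- simulate_deployment(config)
  paths <- write_deployment(sim, out_dir)
  write_provenance(out_dir, step = "simulate",
                   params = list(seed = config$seed,
                                 n_days = config$n_days,
                                 interval_min = config$interval_min),
                   inputs = character(0))
  message(sprintf("simulate: wrote %d files to %s", length(paths), out_dir))
  invisible(paths)
}

#' Pipeline step: raw loggers to filtered index series
#'
#' Reads the logger and sensor CSVs (plus optional mask windows), runs
#' [compute_index_series()] and writes `index.csv` with a provenance
#' record. Per-filter removal counts are reported via `message()`.
#'
#' @param loggers_csv,sensors_csv,masks_csv input paths (`masks_csv`
#'   optional).
#' @param out_dir output directory.
#' @param site a [site_location()].
#' @param light_threshold,crepuscular_fraction,interval_min,refraction
#'   passed to [compute_index_series()].
#' @return The index data.frame, invisibly.
#' @export
pipeline_index <- function(loggers_csv, sensors_csv, out_dir, site,
                           masks_csv = NULL, light_threshold = 0,
                           crepuscular_fraction = 0.1, interval_min = 30,
                           refraction = FALSE) {
  loggers <- read_logger_csv(loggers_csv)
  meta <- read_sensor_meta(sensors_csv)
  masks <- if (!is.null(masks_csv)) read_mask_windows(masks_csv) else NULL
  idx <- compute_index_series(loggers, meta, site, mask_windows = masks,
                              light_threshold = light_threshold,
                              crepuscular_fraction = crepuscular_fraction,
                              interval_min = interval_min,
                              refraction = refraction)
  counts <- colSums(attr(idx, "counts"))
  message(sprintf(
    "index: %d retained, %d night/zero, %d crepuscular, %d masked",
    counts["retained"],
    ifelse(is.na(counts["night_zero"]), 0, counts["night_zero"]),
    ifelse(is.na(counts["crepuscular"]), 0, counts["crepuscular"]),
    ifelse(is.na(counts["masked"]), 0, counts["masked"])))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_index_csv(idx, file.path(out_dir, "index.csv"))
  write_provenance(out_dir, step = "index",
                   params = list(light_threshold = light_threshold,
                                 crepuscular_fraction = crepuscular_fraction,
                                 interval_min = interval_min,
                                 site = unclass(site)),
                   inputs = c(loggers_csv, sensors_csv, masks_csv))
  invisible(idx)
}

#' Pipeline step: index series to seasonal trend outputs
#'
#' Fits [canopy_trend()] to an index CSV and writes `trend.csv` (the
#' smoothed daily trend per sensor), `summary.json` (per-sensor extrema
#' and cross-sensor mean/SE, on the index scale and — when `k_a` is given
#' — the thallus-area-index scale) and, if a daily reference radiation CSV
#' is supplied, `drift.json` from [drift_check()].
#'
#' @param index_csv path to an index CSV from [pipeline_index()].
#' @param out_dir output directory.
#' @param span,degree,robust_iter,aggregate,k_a passed to
#'   [canopy_trend()].
#' @param reference_csv optional daily reference CSV with columns `date`
#'   and `radiation`.
#' @return The [canopy_trend()] fit, invisibly.
#' @export
pipeline_trend <- function(index_csv, out_dir, span = 0.4, degree = 1,
                           robust_iter = 0, aggregate = "points",
                           k_a = NULL, reference_csv = NULL) {
  idx <- read_index_csv(index_csv)
  fit <- canopy_trend(idx, span = span, degree = degree,
                      robust_iter = robust_iter, aggregate = aggregate,
                      k_a = k_a)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trend <- predict(fit)
  utils::write.csv(trend, file.path(out_dir, "trend.csv"),
                   row.names = FALSE, quote = FALSE)
  s <- summary(fit)
  js <- list(n_sensors = s$n_sensors,
             span = span, degree = degree, aggregate = aggregate,
             per_sensor = as.data.frame(s$extrema),
             index_scale = list(mean = as.list(s$mean),
                                se = as.list(s$se)))
  if (!is.null(k_a))
    js$tai_scale <- list(k_a = k_a, mean = as.list(s$tai_mean),
                         se = as.list(s$tai_se))
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(reference_csv)) {
    ref <- utils::read.csv(reference_csv, stringsAsFactors = FALSE)
    daily <- daily_open_means(idx)
    m <- merge(daily, data.frame(date = as.Date(ref$date),
                                 radiation = ref$radiation), by = "date")
    dr <- drift_check(m$date, m$logger, m$radiation)
    jsonlite::write_json(unclass(dr), file.path(out_dir, "drift.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_provenance(out_dir, step = "trend",
                   params = list(span = span, degree = degree,
                                 robust_iter = robust_iter,
                                 aggregate = aggregate, k_a = k_a),
                   inputs = c(index_csv, reference_csv))
  invisible(fit)
}

#' Daily means of the open-rock reference from an index table
#'
#' Convenience for [drift_check()]: averages the `I_o` column of an index
#' series over calendar days (daylight records only are present after
#' filtering upstream; here all non-missing `I_o` values are used).
#'
#' @param idx index data.frame with `timestamp` and `I_o`.
#' @return Data.frame with `date` and `logger` (daily mean `I_o`).
#' @export
daily_open_means <- function(idx) {
  one <- idx[idx$sensor_id == idx$sensor_id[1], , drop = FALSE]
  d <- as.Date(one$timestamp, tz = "UTC")
  mn <- tapply(one$I_o, d, mean, na.rm = TRUE)
  data.frame(date = as.Date(names(mn)), logger = as.numeric(mn))
}

write_provenance <- function(out_dir, step, params, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  inputs <- unlist(inputs, use.names = FALSE)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  prov <- list(step = step,
               package = "canopylux",
               version = as.character(utils::packageVersion("canopylux")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               params = params,
               input_md5 = hashes)
  jsonlite::write_json(prov,
                       file.path(out_dir,
                                 paste0("provenance-", step, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(prov)
}
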