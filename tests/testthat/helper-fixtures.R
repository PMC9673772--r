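# Shared fixtures: tiny deterministic configs and CSV writers.

# noise-free, idealized sensors: the pipeline should be exact.
# overrides of noise/surface/sensor merge into (and can undo) the presets.
quiet_config <- function(...) {
  presets <- list(noise = list(sigma_open = 0, sigma_canopy = 0),
                  surface = list(cloud_sigma = 0),
                  sensor = list(floor_lux = 0, quantization_lux = 0))
  over <- list(...)
  for (nm in names(over)) {
    presets[[nm]] <- if (nm %in% c("noise", "surface", "sensor"))
      utils::modifyList(presets[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(sim_config, presets)
}

furbo <- site_location(53.246, -9.221, 0)

# write a small long-format logger CSV; rows is a data.frame with
# timestamp (character), sensor_id, light_lux, temp_c
write_toy_loggers <- function(rows, path = tempfile(fileext = ".csv"),
                              preamble = NULL) {
  con <- file(path, "w")
  if (!is.null(preamble)) writeLines(preamble, con)
  writeLines("timestamp,sensor_id,light_lux,temp_c", con)
  writeLines(do.call(paste, c(lapply(rows, as.character), sep = ",")), con)
  close(con)
  path
}

toy_meta <- function(ids, roles) {
  data.frame(sensor_id = ids, role = roles, stringsAsFactors = FALSE)
}
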