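# fixture builders: tiny grids and observation files assembled in code

# grid whose cell value is fill(lat, lon, year, month); fill may be a
# constant
make_grid <- function(lat, lon, years = 1984L, months = c(4L, 5L, 6L),
                      fill = 15) {
  f <- if (is.function(fill)) fill else function(la, lo, y, m) fill
  arr <- array(NA_real_, dim = c(length(lat), length(lon), length(years),
                                 length(months)))
  for (k in seq_along(years)) for (m in seq_along(months)) {
    arr[, , k, m] <- outer(lat, lon, function(la, lo)
      rep_len(f(la, lo, years[k], months[m]), length(la)))
  }
  temp_grid(lat, lon, years, months, arr)
}

write_obs_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

obs_header <- "route_id,latitude,longitude,year,species_id,count"

# minimal deterministic scenario shared by synthetic-data tests
tiny_cfg <- function(...) {
  args <- list(lat_range = c(30, 44), lon_range = c(-100, -97),
               grid_res = 0.5, route_spacing = 0.5, route_jitter = 0.1,
               lapse_rate = 1, warming = 0.43, noise_sd = 0,
               spatial_sd = 0, seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}
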