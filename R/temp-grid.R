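#' Monthly mean-temperature grid
#'
#' In-memory container for a stack of gridded monthly mean temperatures:
#' a regular latitude-longitude lattice of cell centers with one layer per
#' (year, month). Values are degrees Celsius; cells without data may be
#' `NA`. Built directly by [generate_climate()] or read from a long-format
#' CSV by [load_temperature_grid()].
#'
#' @param lat,lon Ascending vectors of cell-center coordinates (decimal
#'   degrees; longitude negative west).
#' @param years,months Integer vectors labelling the third and fourth array
#'   dimensions.
#' @param values Numeric array with dim
#'   `c(length(lat), length(lon), length(years), length(months))`.
#' @return An object of class `temp_grid`.
#' @export
temp_grid <- function(lat, lon, years, months, values) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  years <- as.integer(years); months <- as.integer(months)
  if (is.unsorted(lat) || is.unsorted(lon))
    stop("temp_grid: lat and lon must be ascending")
  if (!identical(dim(values),
                 c(length(lat), length(lon), length(years), length(months))))
    stop("temp_grid: values array dimensions do not match coordinates")
  dimnames(values) <- list(NULL, NULL, as.character(years), as.character(months))
  structure(
    list(lat = lat, lon = lon, years = years, months = months,
         values = values),
    class = "temp_grid"
  )
}

#' @export
print.temp_grid <- function(x, ...) {
  cat(sprintf(
    "<temp_grid> %d x %d cells, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
    length(x$lat), length(x$lon), min(x$lat), max(x$lat),
    min(x$lon), max(x$lon)))
  cat(sprintf("  years %s; months %s\n",
              paste(range(x$years), collapse = "-"),
              paste(x$months, collapse = ",")))
  invisible(x)
}

#' Read a monthly temperature grid from long-format CSV
#'
#' Expects columns `latitude`, `longitude`, `year`, `month`, `tmean_c`, one
#' row per cell x year x month. The set of distinct latitudes and
#' longitudes defines the lattice; cells missing a given layer are `NA`.
#' Coverage of the breeding-season months (April-June by default) is
#' verified for the requested years: a layer entirely absent from the file
#' is a fatal error naming the missing `(year, month)` pairs. Months
#' outside `required_months` (e.g. July-September layers) are loaded but
#' never indexed by the analysis.
#'
#' @param source Path to a CSV file.
#' @param years Years whose coverage must be complete; default all years in
#'   the file.
#' @param required_months Months that must be present for every year in
#'   `years` (default April-June).
#' @return A [temp_grid()].
#' @export
load_temperature_grid <- function(source, years = NULL,
                                  required_months = c(4L, 5L, 6L)) {
  d <- utils::read.table(source, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  need <- c("latitude", "longitude", "year", "month", "tmean_c")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("load_temperature_grid: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  lat <- sort(unique(as.numeric(d$latitude)))
  lon <- sort(unique(as.numeric(d$longitude)))
  yrs <- sort(unique(as.integer(d$year)))
  mns <- sort(unique(as.integer(d$month)))
  if (is.null(years)) years <- yrs

  have <- unique(d[, c("year", "month")])
  wanted <- expand.grid(year = years, month = required_months)
  key <- function(y, m) paste(y, m, sep = "\r")
  miss <- !(key(wanted$year, wanted$month) %in% key(have$year, have$month))
  if (any(miss)) {
    stop("load_temperature_grid: missing monthly layer(s): ",
         paste(sprintf("(%d, %d)", wanted$year[miss], wanted$month[miss]),
               collapse = ", "))
  }

  arr <- array(NA_real_, dim = c(length(lat), length(lon),
                                 length(yrs), length(mns)))
  i <- match(as.numeric(d$latitude), lat)
  j <- match(as.numeric(d$longitude), lon)
  k <- match(as.integer(d$year), yrs)
  m <- match(as.integer(d$month), mns)
  arr[cbind(i, j, k, m)] <- as.numeric(d$tmean_c)
  temp_grid(lat, lon, yrs, mns, arr)
}

#' Write a temperature grid to long-format CSV
#'
#' Inverse of [load_temperature_grid()]; `NA` cells are dropped.
#'
#' @param grid A [temp_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(grid, path) {
  stopifnot(inherits(grid, "temp_grid"))
  g <- expand.grid(latitude = grid$lat, longitude = grid$lon,
                   year = grid$years, month = grid$months,
                   KEEP.OUT.ATTRS = FALSE)
  g$tmean_c <- as.vector(grid$values)
  g <- g[!is.na(g$tmean_c), ]
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Linear indices (into an n_lat x n_lon layer matrix) of the cells whose
# centers lie within buffer_km great-circle km of (latitude, longitude).
# A bounding box in degrees prunes candidates before the haversine test.
.buffer_cells <- function(grid, latitude, longitude, buffer_km) {
  dlat <- buffer_km / KM_PER_DEGREE_LAT
  ii <- which(grid$lat >= latitude - dlat - 1e-9 &
              grid$lat <= latitude + dlat + 1e-9)
  coslat <- max(cos(latitude * pi / 180), 1e-6)
  dlon <- buffer_km / (KM_PER_DEGREE_LAT * coslat)
  jj <- which(grid$lon >= longitude - dlon - 1e-9 &
              grid$lon <= longitude + dlon + 1e-9)
  if (!length(ii) || !length(jj)) return(integer(0))
  cand <- expand.grid(i = ii, j = jj, KEEP.OUT.ATTRS = FALSE)
  dist_m <- geosphere::distHaversine(
    cbind(grid$lon[cand$j], grid$lat[cand$i]),
    c(longitude, latitude),
    r = EARTH_RADIUS_M)
  keep <- dist_m / 1000 <= buffer_km + 1e-9
  (cand$j[keep] - 1L) * length(grid$lat) + cand$i[keep]
}

#' Breeding-season temperature within a buffer of a point
#'
#' Mean breeding-season temperature for one year at one location: the
#' unweighted mean, over grid cells whose centers fall within `buffer_km`
#' great-circle km of the point, of each cell's April-June (by default)
#' monthly-mean average. The 20-km default encloses the entirety of a
#' 39.5-km survey route around its centroid.
#'
#' @param grid A [temp_grid()].
#' @param latitude,longitude Point coordinates (decimal degrees).
#' @param year Calendar year (must be a grid year).
#' @param buffer_km Buffer radius in km.
#' @param months Months averaged into the seasonal mean.
#' @param label Optional name (e.g. a route id) used in error messages.
#' @return Mean temperature in degrees C (scalar).
#' @export
breeding_season_temperature <- function(grid, latitude, longitude, year,
                                        buffer_km = 20,
                                        months = c(4L, 5L, 6L),
                                        label = NULL) {
  routes <- data.frame(route_id = if (is.null(label)) "point" else label,
                       latitude = latitude, longitude = longitude)
  m <- route_breeding_temps(grid, routes, years = year,
                            buffer_km = buffer_km, months = months)
  as.numeric(m[1, 1])
}

#' Per-route, per-year breeding-season temperature matrix
#'
#' Vectorized workhorse behind [breeding_season_temperature()]: computes
#' the buffered seasonal mean for every route x year combination in one
#' pass over the grid layers. Routes whose buffer contains no data cell are
#' a fatal error naming the route.
#'
#' @param grid A [temp_grid()].
#' @param routes Data frame with columns `route_id`, `latitude`,
#'   `longitude` (one row per route).
#' @param years Years to evaluate (subset of the grid years).
#' @inheritParams breeding_season_temperature
#' @return Numeric matrix, `nrow(routes)` x `length(years)`, with
#'   dimnames.
#' @export
route_breeding_temps <- function(grid, routes, years, buffer_km = 20,
                                 months = c(4L, 5L, 6L)) {
  stopifnot(inherits(grid, "temp_grid"))
  years <- as.integer(years); months <- as.integer(months)
  if (!all(years %in% grid$years))
    stop("route_breeding_temps: year(s) not in grid: ",
         paste(setdiff(years, grid$years), collapse = ", "))
  if (!all(months %in% grid$months))
    stop("route_breeding_temps: month(s) not in grid: ",
         paste(setdiff(months, grid$months), collapse = ", "))

  cells <- lapply(seq_len(nrow(routes)), function(r)
    .buffer_cells(grid, routes$latitude[r], routes$longitude[r], buffer_km))
  none <- lengths(cells) == 0L
  if (any(none))
    stop("route_breeding_temps: no grid cell center within ", buffer_km,
         " km of route(s): ",
         paste(routes$route_id[none], collapse = ", "))

  idx_all <- unlist(cells)
  rf <- rep(seq_len(nrow(routes)), lengths(cells))
  out <- matrix(NA_real_, nrow(routes), length(years),
                dimnames = list(routes$route_id, years))
  ki <- match(years, grid$years)
  mi <- match(months, grid$months)
  for (y in seq_along(years)) {
    acc <- numeric(length(idx_all))
    nok <- numeric(length(idx_all))
    for (m in mi) {
      v <- grid$values[, , ki[y], m][idx_all]
      ok <- !is.na(v)
      acc <- acc + ifelse(ok, v, 0)
      nok <- nok + ok
    }
    season <- ifelse(nok == length(mi), acc / length(mi), NA_real_)
    good <- !is.na(season)
    ssum <- rowsum(ifelse(good, season, 0), rf)
    scnt <- rowsum(as.numeric(good), rf)
    val <- ssum / scnt
    val[scnt == 0] <- NA_real_
    out[, y] <- val
  }
  bad <- which(is.na(out), arr.ind = TRUE)
  if (nrow(bad)) {
    ex <- utils::head(unique(routes$route_id[bad[, 1]]), 5L)
    stop("route_breeding_temps: no data in buffer for route(s) ",
         paste(ex, collapse = ", "), " in at least one requested year")
  }
  out
}
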