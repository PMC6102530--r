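#' Load survey observations from a delimited file
#'
#' Reads a BBS-like table of per-route, per-year species counts. The file
#' must have a header naming the six required fields `route_id`,
#' `latitude`, `longitude`, `year`, `species_id`, `count`; a missing column
#' is fatal. Rows with non-numeric or negative counts, or unparseable
#' coordinates/years, are rejected with a warning listing their file line
#' numbers. Duplicate (route, species, year) rows have their counts summed,
#' with a warning.
#'
#' @param source Path to a CSV (default) or TSV file; the delimiter is
#'   inferred from the extension unless `sep` is given.
#' @param sep Field delimiter; `NULL` to infer (`"\t"` for `.tsv`/`.txt`,
#'   `","` otherwise).
#' @return A data frame of observation records with typed columns
#'   `route_id`, `latitude`, `longitude`, `year`, `species_id`, `count`.
#' @export
load_survey_observations <- function(source, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", source, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  required <- c("route_id", "latitude", "longitude", "year",
                "species_id", "count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("load_survey_observations: missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  yr <- suppressWarnings(as.integer(raw$year))
  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(lat) | is.na(lon) | is.na(yr) | is.na(cnt) |
                 cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    # +1 for the header line
    warning(sprintf(
      "load_survey_observations: rejected %d malformed row(s) at line(s) %s",
      length(bad), paste(bad + 1L, collapse = ", ")))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  obs <- data.frame(
    route_id = raw$route_id[keep],
    latitude = lat[keep],
    longitude = lon[keep],
    year = yr[keep],
    species_id = raw$species_id[keep],
    count = as.integer(cnt[keep]),
    stringsAsFactors = FALSE
  )

  key <- paste(obs$route_id, obs$species_id, obs$year, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf(
      "load_survey_observations: summed counts for %d duplicated (route, species, year) row(s)",
      ndup))
    first <- !duplicated(key)
    counts <- rowsum(obs$count, key, reorder = FALSE)
    merged <- obs[first, ]
    merged$count <- as.integer(counts[match(key[first], rownames(counts)), 1])
    obs <- merged
  }
  rownames(obs) <- NULL
  obs
}

#' Write survey observations to CSV
#'
#' Writes the exact format [load_survey_observations()] reads.
#'
#' @param obs Observation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_observations <- function(obs, path) {
  cols <- c("route_id", "latitude", "longitude", "year", "species_id", "count")
  utils::write.csv(obs[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observation-year conditional route temperatures for all species
#'
#' For every species x route combination occupied (count > 0) during a
#' period, computes the mean breeding-season temperature over only those
#' years in which the species was observed on the route, together with the
#' total count over those years. Conditioning temperature on observation
#' years ties the thermal measurement to the conditions the birds actually
#' bred under.
#'
#' @param obs Observation data frame (see [load_survey_observations()]).
#' @param grid A [temp_grid()].
#' @param period A [period_window()].
#' @inheritParams breeding_season_temperature
#' @return Data frame with one row per occupied species x route:
#'   `species_id`, `route_id`, `latitude`, `longitude`, `period`,
#'   `mean_breeding_T`, `n_years`, `total_count`.
#' @export
species_route_temperatures <- function(obs, grid, period, buffer_km = 20,
                                       months = c(4L, 5L, 6L)) {
  stopifnot(inherits(period, "period_window"))
  sub <- obs[obs$year %in% period_years(period) & obs$count > 0, ]
  if (!nrow(sub)) {
    return(data.frame(species_id = character(), route_id = character(),
                      latitude = numeric(), longitude = numeric(),
                      period = character(), mean_breeding_T = numeric(),
                      n_years = integer(), total_count = integer(),
                      stringsAsFactors = FALSE))
  }
  routes <- sub[!duplicated(sub$route_id),
                c("route_id", "latitude", "longitude")]
  yrs <- sort(unique(sub$year))
  tm <- route_breeding_temps(grid, routes, yrs, buffer_km = buffer_km,
                             months = months)
  ri <- match(sub$route_id, routes$route_id)
  yi <- match(sub$year, yrs)
  tvals <- tm[cbind(ri, yi)]

  key <- paste(sub$species_id, sub$route_id, sep = "\r")
  first <- !duplicated(key)
  tsum <- rowsum(tvals, key, reorder = FALSE)
  csum <- rowsum(sub$count, key, reorder = FALSE)
  nyr <- rowsum(rep(1L, nrow(sub)), key, reorder = FALSE)
  ord <- match(key[first], rownames(tsum))
  out <- data.frame(
    species_id = sub$species_id[first],
    route_id = sub$route_id[first],
    latitude = sub$latitude[first],
    longitude = sub$longitude[first],
    period = period$label,
    mean_breeding_T = tsum[ord, 1] / nyr[ord, 1],
    n_years = as.integer(nyr[ord, 1]),
    total_count = as.integer(csum[ord, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$species_id, out$route_id), ]
  rownames(out) <- NULL
  out
}

#' Route temperature for one species on one route in one period
#'
#' Single-record form of [species_route_temperatures()]. It is an error to
#' request a (species, route) pair never observed (count > 0) within the
#' period.
#'
#' @inheritParams species_route_temperatures
#' @param species_id,route_id Identifiers selecting the record.
#' @return One-row data frame as in [species_route_temperatures()], plus a
#'   `years_used` attribute holding the contributing years.
#' @export
species_period_route_temperature <- function(obs, grid, species_id, route_id,
                                             period, buffer_km = 20,
                                             months = c(4L, 5L, 6L)) {
  sub <- obs[obs$species_id == species_id & obs$route_id == route_id, ]
  res <- species_route_temperatures(sub, grid, period,
                                    buffer_km = buffer_km, months = months)
  if (!nrow(res))
    stop(sprintf(
      "species_period_route_temperature: species '%s' never observed on route '%s' in period '%s'",
      species_id, route_id, period$label))
  yrs <- sort(unique(sub$year[sub$year %in% period_years(period) &
                                sub$count > 0]))
  attr(res, "years_used") <- yrs
  res
}
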