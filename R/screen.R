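#' Species and study-region screening criteria
#'
#' Thresholds applied before any range-margin analysis, mirroring
#' conservative selection rules for continental survey data: the study
#' region is clipped below a maximum latitude (low sampling density further
#' north); a species' historical poleward margin must lie far enough south
#' of the study edge that poleward expansion is detectable; and species
#' that are scarce (few individuals) or rare (few occupied routes) in
#' either period are excluded. Qualitative exclusions (highly disjunct
#' populations, principally coastal species, non-natives) carry no formula
#' and are expressed as an explicit manual list, never inferred.
#'
#' @param max_study_latitude Routes at or above this latitude (degrees N)
#'   are removed from the study region (default 52; the clip is strict,
#'   i.e. latitude must be < 52).
#' @param max_historical_poleward_margin Maximum occupied-route latitude in
#'   the historical period allowed for a species to be retained
#'   (default 49, inclusive).
#' @param min_individuals_per_period Minimum summed count in each period
#'   (default 100; species with fewer are excluded).
#' @param min_routes_per_period Minimum unique occupied routes in each
#'   period (default 30).
#' @param manual_exclusions Named character vector: names are species ids,
#'   values are non-empty reason strings.
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(max_study_latitude = 52,
                               max_historical_poleward_margin = 49,
                               min_individuals_per_period = 100,
                               min_routes_per_period = 30,
                               manual_exclusions = character()) {
  stopifnot(max_study_latitude > 0,
            max_historical_poleward_margin > 0,
            min_individuals_per_period > 0,
            min_routes_per_period > 0)
  if (length(manual_exclusions)) {
    if (is.null(names(manual_exclusions)) ||
        any(!nzchar(names(manual_exclusions))) ||
        any(!nzchar(manual_exclusions)))
      stop("screening_criteria: manual_exclusions must be a named vector of non-empty reasons")
  }
  structure(
    list(max_study_latitude = max_study_latitude,
         max_historical_poleward_margin = max_historical_poleward_margin,
         min_individuals_per_period = min_individuals_per_period,
         min_routes_per_period = min_routes_per_period,
         manual_exclusions = manual_exclusions),
    class = "screening_criteria"
  )
}

#' Clip observations to the study region
#'
#' Removes records on routes whose centroid latitude is at or above the
#' study's northern bound (strictly-less-than retention: a route at exactly
#' the bound is removed). The number of removed routes is reported via
#' `message()`.
#'
#' @param obs Observation data frame.
#' @param criteria A [screening_criteria()].
#' @return The filtered observation data frame.
#' @export
clip_study_region <- function(obs, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  drop <- obs$latitude >= criteria$max_study_latitude
  n_routes_dropped <- length(unique(obs$route_id[drop]))
  if (n_routes_dropped > 0)
    message(sprintf("clip_study_region: removed %d route(s) at >= %g degrees N",
                    n_routes_dropped, criteria$max_study_latitude))
  out <- obs[!drop, ]
  rownames(out) <- NULL
  out
}

#' Screen species against the selection criteria
#'
#' A species is retained iff it passes every criterion: not manually
#' excluded; total individuals at least `min_individuals_per_period` in
#' each of the two periods; unique occupied routes at least
#' `min_routes_per_period` in each period; and maximum occupied-route
#' latitude in the historical (first) period at most
#' `max_historical_poleward_margin`. Criteria are evaluated independently,
#' so the retained set does not depend on the order of application; the
#' report records per-criterion outcomes and the first failure in the
#' fixed order manual, individuals, routes, margin.
#'
#' @param obs Observation data frame (already clipped to the study region).
#' @param criteria A [screening_criteria()].
#' @param period1,period2 The historical and later [period_window()]s.
#' @return A list with `retained` (character vector of species ids) and
#'   `report` (data frame, one row per species with per-criterion columns).
#' @export
filter_species <- function(obs, criteria, period1, period2) {
  stopifnot(inherits(criteria, "screening_criteria"),
            inherits(period1, "period_window"),
            inherits(period2, "period_window"))
  occ <- obs[obs$count > 0, ]
  species <- sort(unique(occ$species_id))
  if (!length(species)) {
    warning("filter_species: no species present in the observations")
    return(list(retained = character(),
                report = data.frame(species_id = character())))
  }

  per_period <- function(period) {
    sub <- occ[occ$year %in% period_years(period), ]
    ind <- rowsum(sub$count, sub$species_id)
    rts <- tapply(sub$route_id, sub$species_id,
                  function(r) length(unique(r)))
    list(
      individuals = ind[match(species, rownames(ind)), 1],
      routes = as.integer(rts[match(species, names(rts))])
    )
  }
  s1 <- per_period(period1)
  s2 <- per_period(period2)
  sub1 <- occ[occ$year %in% period_years(period1), ]
  maxlat <- tapply(sub1$latitude, sub1$species_id, max)
  maxlat <- as.numeric(maxlat[match(species, names(maxlat))])

  zero_na <- function(x) ifelse(is.na(x), 0, x)
  pass_manual <- !(species %in% names(criteria$manual_exclusions))
  pass_ind <- zero_na(s1$individuals) >= criteria$min_individuals_per_period &
    zero_na(s2$individuals) >= criteria$min_individuals_per_period
  pass_routes <- zero_na(s1$routes) >= criteria$min_routes_per_period &
    zero_na(s2$routes) >= criteria$min_routes_per_period
  # a species absent from period 1 has no historical margin; it already
  # fails the abundance criterion, and the margin test is recorded as fail
  pass_margin <- !is.na(maxlat) &
    maxlat <= criteria$max_historical_poleward_margin

  retained <- pass_manual & pass_ind & pass_routes & pass_margin
  first_fail <- rep(NA_character_, length(species))
  first_fail[!pass_margin] <- "max_historical_poleward_margin"
  first_fail[!pass_routes] <- "min_routes_per_period"
  first_fail[!pass_ind] <- "min_individuals_per_period"
  first_fail[!pass_manual] <- "manual_exclusion"

  report <- data.frame(
    species_id = species,
    n_individuals_p1 = as.integer(zero_na(s1$individuals)),
    n_individuals_p2 = as.integer(zero_na(s2$individuals)),
    n_routes_p1 = zero_na(s1$routes),
    n_routes_p2 = zero_na(s2$routes),
    max_latitude_p1 = maxlat,
    pass_manual = pass_manual,
    pass_min_individuals = pass_ind,
    pass_min_routes = pass_routes,
    pass_max_margin = pass_margin,
    retained = retained,
    first_failed = first_fail,
    stringsAsFactors = FALSE
  )
  if (!any(retained))
    warning("filter_species: no species passed all criteria")
  list(retained = species[retained], report = report)
}

#' Write the screening report to CSV
#'
#' @param screen Result of [filter_species()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(screen, path) {
  utils::write.csv(screen$report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
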