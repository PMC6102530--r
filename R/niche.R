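#' Abundance-weighted mean temperature over a set of routes
#'
#' The temperature summary used for margin and thermal-limit sets: each
#' member route's observation-year mean breeding-season temperature is
#' weighted by the species' total abundance on the route over those years,
#' so routes supporting more individuals count for more. Equal counts
#' reduce to the plain arithmetic mean.
#'
#' @param members Data frame with columns `mean_breeding_T` and
#'   `total_count` (rows of a [species_route_temperatures()] table).
#' @return Weighted mean temperature in degrees C.
#' @export
abundance_weighted_mean_temperature <- function(members) {
  stopifnot(is.data.frame(members),
            all(c("mean_breeding_T", "total_count") %in% names(members)))
  if (!nrow(members))
    stop("abundance_weighted_mean_temperature: empty member set")
  w <- members$total_count
  if (any(w <= 0))
    stop("abundance_weighted_mean_temperature: every member must have total_count > 0")
  sum(members$mean_breeding_T * w) / sum(w)
}

# shared extraction: order one species' route-temperature rows by `by`
# (descending if desc), ties broken by ascending route_id, take k
.extreme_set <- function(route_temps, by, desc, k) {
  if (!nrow(route_temps)) stop("empty occupied-route set")
  sp <- unique(route_temps$species_id)
  if (length(sp) > 1)
    stop("route_temps must contain a single species; got: ",
         paste(sp, collapse = ", "))
  key <- route_temps[[by]]
  ord <- order(if (desc) -key else key, route_temps$route_id)
  n <- min(k, nrow(route_temps))
  list(members = route_temps[ord[seq_len(n)], , drop = FALSE],
       small_set = nrow(route_temps) < k)
}

#' Geographic range-margin route set
#'
#' The range margin of a species in a period is operationalized as its k
#' (default 10) most poleward or most equatorward occupied routes;
#' averaging over k locations buffers the margin estimate against
#' nondetection at any single route. Ties in latitude are broken by
#' ascending `route_id` for determinism. If fewer than k routes are
#' occupied, all are used and `small_set` is flagged.
#'
#' @param route_temps Rows of [species_route_temperatures()] for one
#'   species in one period.
#' @param side `"poleward"` (highest latitudes) or `"equatorward"`.
#' @param k Number of margin routes (default 10).
#' @return An object of class `margin_set` with elements `species_id`,
#'   `period`, `side`, `routes`, `mean_latitude`, `weighted_T`,
#'   `small_set`, and the member rows in `members`.
#' @export
margin_route_set <- function(route_temps,
                             side = c("poleward", "equatorward"),
                             k = 10L) {
  side <- match.arg(side)
  ex <- .extreme_set(route_temps, "latitude", desc = side == "poleward", k)
  m <- ex$members
  structure(
    list(species_id = m$species_id[1],
         period = m$period[1],
         side = side,
         k = k,
         routes = m$route_id,
         mean_latitude = mean(m$latitude),
         weighted_T = abundance_weighted_mean_temperature(m),
         small_set = ex$small_set,
         members = m),
    class = "margin_set"
  )
}

#' Realized thermal-niche limit route set
#'
#' The realized warm (cool) thermal niche limit is the abundance-weighted
#' mean breeding-season temperature over the k (default 10) warmest
#' (coolest) routes where the species was recorded, regardless of where
#' those routes lie geographically. Ties are broken by ascending
#' `route_id`; fewer than k occupied routes sets `small_set`.
#'
#' @inheritParams margin_route_set
#' @param direction `"warm"` or `"cool"`.
#' @return An object of class `thermal_limit_set` with elements
#'   `species_id`, `period`, `direction`, `routes`, `weighted_T`,
#'   `small_set`, `members`.
#' @export
thermal_limit_route_set <- function(route_temps,
                                    direction = c("warm", "cool"),
                                    k = 10L) {
  direction <- match.arg(direction)
  ex <- .extreme_set(route_temps, "mean_breeding_T",
                     desc = direction == "warm", k)
  m <- ex$members
  structure(
    list(species_id = m$species_id[1],
         period = m$period[1],
         direction = direction,
         k = k,
         routes = m$route_id,
         weighted_T = abundance_weighted_mean_temperature(m),
         small_set = ex$small_set,
         members = m),
    class = "thermal_limit_set"
  )
}

#' @export
print.margin_set <- function(x, ...) {
  cat(sprintf(
    "<margin_set> %s / %s / %s: %d routes, mean lat %.3f, weighted T %.3f C%s\n",
    x$species_id, x$period, x$side, length(x$routes), x$mean_latitude,
    x$weighted_T, if (x$small_set) " [small set]" else ""))
  invisible(x)
}

#' @export
print.thermal_limit_set <- function(x, ...) {
  cat(sprintf(
    "<thermal_limit_set> %s / %s / %s: %d routes, weighted T %.3f C%s\n",
    x$species_id, x$period, x$direction, length(x$routes), x$weighted_T,
    if (x$small_set) " [small set]" else ""))
  invisible(x)
}

#' Thermal niche centroid
#'
#' Abundance-weighted mean breeding-season temperature over all occupied
#' routes of the species in the period -- the reference point from which
#' breadth-adjusted temperatures are measured.
#'
#' @inheritParams margin_route_set
#' @return Centroid temperature in degrees C.
#' @export
niche_centroid <- function(route_temps) {
  sp <- unique(route_temps$species_id)
  if (length(sp) > 1)
    stop("niche_centroid: route_temps must contain a single species")
  abundance_weighted_mean_temperature(route_temps)
}

#' Breadth-adjusted temperature
#'
#' Expresses a margin or limit temperature relative to the species' thermal
#' niche centroid, removing between-species differences in niche position
#' before margins and limits are regressed against one another. The default
#' is the signed deviation `t - centroid_t`; `method = "scaled"` divides
#' that deviation by the species' total niche breadth (warm limit minus
#' cool limit), for a dimensionless alternative.
#'
#' @param t Temperature(s) to adjust (degrees C).
#' @param centroid_t Niche centroid temperature (degrees C).
#' @param method `"deviation"` (default) or `"scaled"`.
#' @param breadth Total niche breadth in degrees C; required for
#'   `method = "scaled"`.
#' @return Adjusted temperature (degrees C, or dimensionless if scaled).
#' @export
breadth_adjusted_temperature <- function(t, centroid_t,
                                         method = c("deviation", "scaled"),
                                         breadth = NULL) {
  method <- match.arg(method)
  dev <- t - centroid_t
  if (method == "deviation") return(dev)
  if (is.null(breadth) || any(breadth <= 0))
    stop("breadth_adjusted_temperature: scaled method needs breadth > 0")
  dev / breadth
}

#' Environmental distance between a range margin and a thermal limit
#'
#' The temperature gap (degrees C) separating a range margin from the
#' corresponding realized thermal-niche boundary: poleward margins pair
#' with the cool limit (gap = margin T - cool limit T) and equatorward
#' margins with the warm limit (gap = warm limit T - margin T). Because
#' margin and limit are extracted from the same occupied-route pool, the
#' unweighted gaps are nonnegative by construction; with abundance
#' weighting they remain nonnegative whenever temperature declines with
#' latitude across the occupied routes (weighting can in principle invert
#' the ordering on pathological count patterns, so the sign is reported,
#' not clamped). A gap near zero means the margin sits at
#' the species' realized thermal extreme; a large gap means the margin is
#' well inside the tolerated range.
#'
#' @param margin A [margin_route_set()].
#' @param limit A [thermal_limit_route_set()] for the same species and
#'   period; poleward requires `direction = "cool"`, equatorward `"warm"`.
#' @return Environmental distance in degrees C.
#' @export
environmental_distance <- function(margin, limit) {
  stopifnot(inherits(margin, "margin_set"),
            inherits(limit, "thermal_limit_set"))
  if (!identical(margin$species_id, limit$species_id) ||
      !identical(margin$period, limit$period))
    stop("environmental_distance: margin and limit must share species and period")
  expected <- c(poleward = "cool", equatorward = "warm")[margin$side]
  if (!identical(unname(expected), limit$direction))
    stop(sprintf(
      "environmental_distance: %s margin must pair with the %s limit, got %s",
      margin$side, expected, limit$direction))
  if (margin$side == "poleward")
    margin$weighted_T - limit$weighted_T
  else
    limit$weighted_T - margin$weighted_T
}

#' Per-species niche and margin metrics for one period
#'
#' Convenience wrapper assembling, for a single species x period, the four
#' extreme-route sets, the niche centroid, and both environmental
#' distances into a one-row data frame.
#'
#' @inheritParams margin_route_set
#' @return One-row data frame with columns `species_id`, `period`,
#'   `n_routes`, `centroid_T`, `poleward_margin_lat`, `poleward_margin_T`,
#'   `equatorward_margin_lat`, `equatorward_margin_T`, `cool_limit_T`,
#'   `warm_limit_T`, `env_distance_poleward`, `env_distance_equatorward`,
#'   `small_set`.
#' @export
species_niche_metrics <- function(route_temps, k = 10L) {
  pole <- margin_route_set(route_temps, "poleward", k)
  eq <- margin_route_set(route_temps, "equatorward", k)
  cool <- thermal_limit_route_set(route_temps, "cool", k)
  warm <- thermal_limit_route_set(route_temps, "warm", k)
  data.frame(
    species_id = pole$species_id,
    period = pole$period,
    n_routes = nrow(route_temps),
    centroid_T = niche_centroid(route_temps),
    poleward_margin_lat = pole$mean_latitude,
    poleward_margin_T = pole$weighted_T,
    equatorward_margin_lat = eq$mean_latitude,
    equatorward_margin_T = eq$weighted_T,
    cool_limit_T = cool$weighted_T,
    warm_limit_T = warm$weighted_T,
    env_distance_poleward = environmental_distance(pole, cool),
    env_distance_equatorward = environmental_distance(eq, warm),
    small_set = pole$small_set,
    stringsAsFactors = FALSE
  )
}
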