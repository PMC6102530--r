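#' Fixed-site abundance and temperature change for one extreme-route set
#'
#' Holds the historical (period-1) margin or thermal-limit routes constant
#' and asks how the species' abundance and the local climate changed there
#' by period 2. A site's abundance in a period is the summed count over the
#' period's observation years; absence in period 2 (count 0) marks a local
#' population extinction. Temperature change uses all years of each period
#' (not observation-conditional). Extinct sites can be excluded to guard
#' against apparent extinctions that are really nondetections.
#'
#' @param obs Observation data frame.
#' @param grid A [temp_grid()].
#' @param site_set A period-1 [margin_route_set()] or
#'   [thermal_limit_route_set()].
#' @param period1,period2 The two [period_window()]s; `site_set` must come
#'   from `period1`.
#' @param include_extinct Include sites extinct in period 2 (default TRUE)?
#' @inheritParams breeding_season_temperature
#' @return One-row data frame of class `fixed_site_change` with columns
#'   `species_id`, `site_class`, `mean_delta_abundance`, `mean_delta_T`,
#'   `n_sites`, `n_extinct_sites`, `include_extinct`.
#' @export
fixed_site_changes <- function(obs, grid, site_set, period1, period2,
                               include_extinct = TRUE, buffer_km = 20,
                               months = c(4L, 5L, 6L)) {
  is_margin <- inherits(site_set, "margin_set")
  is_limit <- inherits(site_set, "thermal_limit_set")
  if (!is_margin && !is_limit)
    stop("fixed_site_changes: site_set must be a margin_set or thermal_limit_set")
  if (!identical(site_set$period, period1$label))
    stop("fixed_site_changes: site_set must come from period1 ('",
         period1$label, "'), got '", site_set$period, "'")
  site_class <- if (is_margin)
    paste0(site_set$side, "_margin") else paste0(site_set$direction, "_limit")

  sp <- site_set$species_id
  members <- site_set$members
  counts_in <- function(period) {
    sub <- obs[obs$species_id == sp &
                 obs$route_id %in% members$route_id &
                 obs$year %in% period_years(period) & obs$count > 0, ]
    agg <- rowsum(sub$count, sub$route_id)
    out <- agg[match(members$route_id, rownames(agg)), 1]
    ifelse(is.na(out), 0L, out)
  }
  a1 <- counts_in(period1)
  if (any(a1 == 0))
    stop("fixed_site_changes: site(s) never occupied in period 1: ",
         paste(members$route_id[a1 == 0], collapse = ", "))
  a2 <- counts_in(period2)
  extinct <- a2 == 0
  dT <- .route_period_delta_T(members, grid, period1, period2,
                              buffer_km = buffer_km, months = months)
  keep <- if (include_extinct) rep(TRUE, length(a1)) else !extinct
  if (!any(keep)) {
    warning("fixed_site_changes: all sites extinct and excluded; returning NA means")
    mda <- NA_real_; mdt <- NA_real_
  } else {
    mda <- mean((a2 - a1)[keep])
    mdt <- mean(dT[keep])
  }
  structure(
    data.frame(species_id = sp, site_class = site_class,
               mean_delta_abundance = mda, mean_delta_T = mdt,
               n_sites = sum(keep), n_extinct_sites = sum(extinct),
               include_extinct = include_extinct,
               stringsAsFactors = FALSE),
    class = c("fixed_site_change", "data.frame")
  )
}

#' Regress abundance change on temperature change across species
#'
#' OLS of per-species mean abundance change on mean temperature change for
#' one site class (e.g. all poleward-margin rows), completing the
#' fixed-site supplement.
#'
#' @param changes Data frame of stacked [fixed_site_changes()] rows.
#' @return A [fit_result()].
#' @export
abundance_temperature_regression <- function(changes) {
  stopifnot(all(c("mean_delta_abundance", "mean_delta_T") %in% names(changes)))
  ok <- stats::complete.cases(changes[, c("mean_delta_abundance",
                                          "mean_delta_T")])
  .ols_fit(changes$mean_delta_T[ok], changes$mean_delta_abundance[ok],
           "abundance_temperature_regression")
}

#' Fixed-site change table over species and site classes
#'
#' Applies [fixed_site_changes()] to a list of period-1 extreme-route sets
#' (any mix of margin and thermal-limit sets across species) under both
#' extinction-handling variants, producing the supplement's 4 site classes
#' x 2 variants structure in long form.
#'
#' @param obs,grid,period1,period2 As in [fixed_site_changes()].
#' @param sets List of period-1 [margin_route_set()] /
#'   [thermal_limit_route_set()] objects.
#' @inheritParams breeding_season_temperature
#' @return Data frame of stacked `fixed_site_change` rows.
#' @export
fixed_site_change_table <- function(obs, grid, sets, period1, period2,
                                    buffer_km = 20, months = c(4L, 5L, 6L)) {
  rows <- list()
  for (s in sets) {
    for (inc in c(TRUE, FALSE)) {
      rows[[length(rows) + 1L]] <- fixed_site_changes(
        obs, grid, s, period1, period2, include_extinct = inc,
        buffer_km = buffer_km, months = months)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
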