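#' Run the full between-period range-shift analysis
#'
#' End-to-end driver: computes observation-year conditional route
#' temperatures in both periods, extracts per-species margin and
#' thermal-limit sets, and assembles (a) a per-species x period niche
#' metrics table and (b) a per-species x side shift table with
#' displacement, per-decade rate, local margin temperature change,
#' expected direction and binary outcome. Species occupied in only one of
#' the two periods are dropped with a warning (no displacement is
#' defined for them).
#'
#' @param obs Observation data frame (already screened/clipped as
#'   desired).
#' @param grid A [temp_grid()].
#' @param period1,period2 Historical and later [period_window()]s.
#' @param k Number of routes per margin/limit set (default 10).
#' @inheritParams breeding_season_temperature
#' @param species Optional character vector restricting the analysis.
#' @return A list of class `range_shift_analysis` with elements
#'   `metrics` (species x period rows from [species_niche_metrics()]),
#'   `shifts` (species x side rows), `route_temps` (list of the two
#'   [species_route_temperatures()] tables), and the periods.
#' @export
analyze_range_shifts <- function(obs, grid, period1, period2, k = 10L,
                                 buffer_km = 20, months = c(4L, 5L, 6L),
                                 species = NULL) {
  rt1 <- species_route_temperatures(obs, grid, period1,
                                    buffer_km = buffer_km, months = months)
  rt2 <- species_route_temperatures(obs, grid, period2,
                                    buffer_km = buffer_km, months = months)
  sp <- intersect(unique(rt1$species_id), unique(rt2$species_id))
  if (!is.null(species)) sp <- intersect(sp, species)
  only_one <- setdiff(union(unique(rt1$species_id), unique(rt2$species_id)),
                      sp)
  if (!is.null(species)) only_one <- intersect(only_one, species)
  if (length(only_one))
    warning("analyze_range_shifts: dropped species occupied in only one period: ",
            paste(only_one, collapse = ", "))
  if (!length(sp))
    stop("analyze_range_shifts: no species occupied in both periods")

  metrics <- list(); shifts <- list()
  for (s in sp) {
    r1 <- rt1[rt1$species_id == s, ]
    r2 <- rt2[rt2$species_id == s, ]
    metrics[[length(metrics) + 1L]] <- species_niche_metrics(r1, k)
    metrics[[length(metrics) + 1L]] <- species_niche_metrics(r2, k)
    for (side in c("poleward", "equatorward")) {
      m1 <- margin_route_set(r1, side, k)
      m2 <- margin_route_set(r2, side, k)
      disp <- margin_displacement_km(m1, m2)
      rate <- per_decade_rate(disp, period1, period2)
      dT <- local_margin_temperature_change(m1, grid, period1, period2,
                                            buffer_km = buffer_km,
                                            months = months)
      oc <- code_shift_outcome(disp, dT)
      shifts[[length(shifts) + 1L]] <- data.frame(
        species_id = s, side = side,
        displacement_km = disp, rate_km_per_decade = rate,
        delta_T_margin = dT,
        expected_direction = oc$expected_direction,
        outcome = oc$outcome, zero_delta_T = oc$zero_delta_T,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(metrics = do.call(rbind, metrics),
         shifts = do.call(rbind, shifts),
         route_temps = list(rt1, rt2),
         period1 = period1, period2 = period2, k = k),
    class = "range_shift_analysis"
  )
}

#' @export
print.range_shift_analysis <- function(x, ...) {
  nsp <- length(unique(x$shifts$species_id))
  cat(sprintf("<range_shift_analysis> %d species, %s vs %s (k = %d)\n",
              nsp, x$period1$label, x$period2$label, x$k))
  for (side in c("poleward", "equatorward")) {
    r <- x$shifts$rate_km_per_decade[x$shifts$side == side]
    cat(sprintf("  %s margin: mean shift %+.2f km/decade (sd %.2f)\n",
                side, mean(r), stats::sd(r)))
  }
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' Reads the keys `periods` (list of label/start_year/end_year entries),
#' `months`, `buffer_km`, `k`, and an optional `screening` block with the
#' [screening_criteria()] thresholds and `manual_exclusions` (a mapping of
#' species id to reason).
#'
#' @param path Path to a YAML file.
#' @return A list with `periods` (list of [period_window()]s), `months`,
#'   `buffer_km`, `k` and `criteria`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$periods) || length(cfg$periods) != 2)
    stop("load_run_config: config must define exactly two periods")
  periods <- lapply(cfg$periods, function(p)
    period_window(p$label, p$start_year, p$end_year))
  names(periods) <- vapply(periods, `[[`, "", "label")
  sc <- cfg$screening
  manual <- character()
  if (!is.null(sc$manual_exclusions))
    manual <- unlist(sc$manual_exclusions)
  criteria <- screening_criteria(
    max_study_latitude = sc$max_study_latitude %||% 52,
    max_historical_poleward_margin =
      sc$max_historical_poleward_margin %||% 49,
    min_individuals_per_period = sc$min_individuals_per_period %||% 100,
    min_routes_per_period = sc$min_routes_per_period %||% 30,
    manual_exclusions = manual
  )
  list(periods = periods,
       months = as.integer(cfg$months %||% c(4L, 5L, 6L)),
       buffer_km = cfg$buffer_km %||% 20,
       k = as.integer(cfg$k %||% 10L),
       criteria = criteria)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
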