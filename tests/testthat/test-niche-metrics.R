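rt_row <- function(route_id, latitude, t, count, species = "sp1",
                   period = "historical") {
  data.frame(species_id = species, route_id = route_id, latitude = latitude,
             longitude = -90, period = period, mean_breeding_T = t,
             n_years = 1L, total_count = count, stringsAsFactors = FALSE)
}

test_that("margin sets take the k latitude-extreme routes with deterministic ties", {
  rt <- rt_row(sprintf("r%02d", 1:12), latitude = 30:41, t = 20:9,
               count = rep(1, 12))
  pole <- margin_route_set(rt, "poleward", k = 10)
  expect_setequal(pole$members$latitude, 32:41)
  expect_false(pole$small_set)
  expect_equal(pole$mean_latitude, mean(32:41))

  eq <- margin_route_set(rt, "equatorward", k = 10)
  expect_setequal(eq$members$latitude, 30:39)

  # exactly k occupied -> all members, flag unset; fewer -> flag set
  rt10 <- rt[1:10, ]
  expect_false(margin_route_set(rt10, "poleward")$small_set)
  expect_setequal(margin_route_set(rt10, "poleward")$routes, rt10$route_id)
  expect_true(margin_route_set(rt[1:5, ], "poleward")$small_set)
  expect_error(margin_route_set(rt[0, ], "poleward"), "empty")

  # tie at the k-th latitude: smaller route_id wins
  rtt <- rt_row(c("r10", "r02", "r01"), latitude = c(40, 35, 35),
                t = c(10, 15, 15), count = 1)
  pole2 <- margin_route_set(rtt, "poleward", k = 2)
  expect_setequal(pole2$routes, c("r10", "r01"))
})

test_that("thermal limit sets take the k thermally extreme routes", {
  rt <- rt_row(sprintf("r%02d", 1:12), latitude = 30:41, t = 1:12,
               count = rep(2, 12))
  cool <- thermal_limit_route_set(rt, "cool", k = 10)
  expect_setequal(cool$members$mean_breeding_T, 1:10)
  expect_equal(cool$weighted_T, 5.5)
  warm <- thermal_limit_route_set(rt, "warm", k = 10)
  expect_setequal(warm$members$mean_breeding_T, 3:12)
  expect_lte(cool$weighted_T, warm$weighted_T)

  # all routes at the same temperature: membership by route_id order
  rteq <- rt_row(sprintf("r%02d", 12:1), latitude = 30:41, t = 8, count = 1)
  s <- thermal_limit_route_set(rteq, "cool", k = 10)
  expect_equal(sort(s$routes), sprintf("r%02d", 1:10))
  expect_equal(s$weighted_T, 8)

  expect_true(thermal_limit_route_set(rt[1:5, ], "warm")$small_set)
})

test_that("margin and limit extraction matches a repeated-scan oracle on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    rt <- random_route_temps(n, lat_ties = i %% 3 == 0, t_ties = i %% 4 == 0)
    rt <- rt[!duplicated(rt$route_id), ]
    for (side in c("poleward", "equatorward")) {
      got <- margin_route_set(rt, side, k = 10)$routes
      want <- ref_topk_routes(rt, "latitude", desc = side == "poleward",
                              k = 10)
      expect_identical(got, want)
    }
    for (dir in c("warm", "cool")) {
      got <- thermal_limit_route_set(rt, dir, k = 10)$routes
      want <- ref_topk_routes(rt, "mean_breeding_T", desc = dir == "warm",
                              k = 10)
      expect_identical(got, want)
    }
  }
})

test_that("abundance weighting follows the weighted-mean formula", {
  eq <- rt_row(c("a", "b", "c"), 40:42, t = c(10, 12, 14), count = 5)
  expect_equal(abundance_weighted_mean_temperature(eq), 12)
  two <- rt_row(c("a", "b"), 40:41, t = c(10, 20), count = c(1, 3))
  expect_equal(abundance_weighted_mean_temperature(two), 17.5)
  one <- rt_row("a", 40, t = 9.2, count = 44)
  expect_equal(abundance_weighted_mean_temperature(one), 9.2)
  bad <- rt_row(c("a", "b"), 40:41, t = c(10, 20), count = c(0, 3))
  expect_error(abundance_weighted_mean_temperature(bad), "total_count > 0")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(1:25, 1)
    rt <- random_route_temps(n)
    expect_equal(abundance_weighted_mean_temperature(rt),
                 ref_weighted_mean(rt$mean_breeding_T, rt$total_count),
                 tolerance = 1e-12)
  }
})

test_that("the niche centroid is the abundance-weighted mean over all occupied routes", {
  one <- rt_row("a", 40, t = 13.7, count = 2)
  expect_equal(niche_centroid(one), 13.7)
  unif <- rt_row(c("a", "b", "c"), 40:42, t = c(5, 10, 18), count = 3)
  expect_equal(niche_centroid(unif), mean(c(5, 10, 18)))
  w <- rt_row(c("a", "b", "c"), 40:42, t = c(5, 10, 15), count = c(1, 1, 2))
  expect_equal(niche_centroid(w), 11.25)
})

test_that("breadth adjustment is a signed deviation from the centroid", {
  expect_equal(breadth_adjusted_temperature(13, 13), 0)
  expect_equal(breadth_adjusted_temperature(8, 13), -5)
  expect_equal(breadth_adjusted_temperature(8, 13, method = "scaled",
                                            breadth = 10), -0.5)
  expect_error(breadth_adjusted_temperature(8, 13, method = "scaled"),
               "breadth")
})

test_that("cool limit <= centroid <= warm limit, and cool-limit deviations are nonpositive", {
  set.seed(9)
  for (i in 1:50) {
    rt <- random_route_temps(sample(5:40, 1))
    rt <- rt[!duplicated(rt$route_id), ]
    cen <- niche_centroid(rt)
    cool <- thermal_limit_route_set(rt, "cool")$weighted_T
    warm <- thermal_limit_route_set(rt, "warm")$weighted_T
    expect_lte(cool, cen + 1e-12)
    expect_gte(warm, cen - 1e-12)
    expect_lte(breadth_adjusted_temperature(cool, cen), 1e-12)
  }
})

test_that("environmental distance pairs margins with their matching limits", {
  rt <- rt_row(sprintf("r%02d", 1:12), latitude = 30:41,
               t = seq(20, 9, by = -1), count = 1)
  pole <- margin_route_set(rt, "poleward")
  cool <- thermal_limit_route_set(rt, "cool")
  warm <- thermal_limit_route_set(rt, "warm")
  # monotone landscape: poleward margin IS the cool-limit set
  expect_setequal(pole$routes, cool$routes)
  expect_equal(environmental_distance(pole, cool), 0)
  eq <- margin_route_set(rt, "equatorward")
  expect_equal(environmental_distance(eq, warm), 0)
  expect_error(environmental_distance(pole, warm), "cool")

  # hand-built sets with a 2.5-degree gap
  m <- pole; m$weighted_T <- 11.5
  l <- cool; l$weighted_T <- 9.0
  expect_equal(environmental_distance(m, l), 2.5)
})

test_that("environmental distances are nonnegative over random synthetic species", {
  # with equal counts the weights cancel and nonnegativity is exact for
  # any temperature/latitude configuration: the coolest-k set minimizes
  # the mean over every k-subset of the same occupied pool
  set.seed(31)
  for (i in 1:100) {
    rt <- random_route_temps(sample(3:40, 1))
    rt <- rt[!duplicated(rt$route_id), ]
    rt$total_count <- 5L
    met <- species_niche_metrics(rt)
    expect_gte(met$env_distance_poleward, -1e-12)
    expect_gte(met$env_distance_equatorward, -1e-12)
  }
  # with abundance weighting the gaps are exactly zero when temperature is
  # strictly monotone in latitude (margin and limit sets coincide)
  for (i in 1:20) {
    rt <- random_route_temps(sample(12:40, 1))
    rt <- rt[!duplicated(rt$route_id), ]
    rt$mean_breeding_T <- 28 - 0.6 * rt$latitude
    met <- species_niche_metrics(rt)
    expect_equal(met$env_distance_poleward, 0)
    expect_equal(met$env_distance_equatorward, 0)
  }
})

test_that("a non-thermal poleward cap opens a poleward gap that thermal margins lack", {
  cfg <- tiny_cfg(lon_range = c(-100, -90), spatial_sd = 1.5,
                  noise_sd = 0.2, warming = 0, seed = 19L)
  cool_iso <- latitude_for_temperature(cfg, 4.5, period = 1)
  tr <- rbind(
    species_truth("free", 7.5, 4.5, 10.5),
    species_truth("capped", 7.5, 4.5, 10.5,
                  poleward_cap_latitude = cool_iso - 3)
  )
  g <- generate_climate(cfg)
  obs <- simulate_observations(cfg, tr, g)
  rt <- species_route_temperatures(obs, g, cfg$period1)
  m_free <- species_niche_metrics(rt[rt$species_id == "free", ])
  m_cap <- species_niche_metrics(rt[rt$species_id == "capped", ])
  # the cap holds the margin ~3 degC warmer than the cool tolerance, which
  # cold interior pockets let the species realize elsewhere
  expect_gt(m_cap$env_distance_poleward, 1.5)
  expect_gt(m_cap$env_distance_poleward,
            m_free$env_distance_poleward + 0.5)
  # the cap leaves the equatorward side untouched
  expect_lt(abs(m_cap$env_distance_equatorward -
                  m_free$env_distance_equatorward), 0.5)
})
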