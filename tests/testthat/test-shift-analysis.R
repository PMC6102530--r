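mk_margin <- function(lat, species = "sp1", side = "poleward",
                      period = "historical", t = 10) {
  rt <- data.frame(species_id = species, route_id = sprintf("r%02d",
                                                            seq_along(lat)),
                   latitude = lat, longitude = -90, period = period,
                   mean_breeding_T = t, n_years = 1L, total_count = 1L,
                   stringsAsFactors = FALSE)
  margin_route_set(rt, side, k = length(lat))
}

p1 <- period_window("historical", 1984, 1988)
p2 <- period_window("modern", 2002, 2006)

test_that("margin displacement converts latitude change to meridian km", {
  a <- mk_margin(c(40, 41))
  expect_equal(margin_displacement_km(a, a), 0)
  b <- mk_margin(c(41, 42), period = "modern")
  expect_equal(margin_displacement_km(a, b), 111.195)
  c <- mk_margin(c(40, 41) - 0.05, period = "modern")
  expect_equal(margin_displacement_km(a, c), -5.55975)
  expect_error(margin_displacement_km(a, mk_margin(41, species = "sp2")),
               "different species")
  expect_error(
    margin_displacement_km(a, mk_margin(41, side = "equatorward")),
    "different sides")
})

test_that("per-decade rates divide by the period midpoint gap", {
  expect_equal(per_decade_rate(9, p1, p2), 5)        # 18-year gap
  expect_equal(per_decade_rate(0, p1, p2), 0)
  expect_equal(per_decade_rate(-8.64, p1, p2), -4.8)
  expect_error(per_decade_rate(1, p1, p1), "identical midpoints")
})

test_that("net extent change subtracts the equatorward from the poleward rate", {
  expect_equal(extent_change_rate(0.65, 5.45), -4.80)
  expect_equal(extent_change_rate(3, 3), 0)
  expect_equal(extent_change_rate(2, -1), 3)
  # antisymmetry under swapping the margins' roles
  set.seed(2)
  for (i in 1:20) {
    r <- rnorm(2, sd = 5)
    expect_equal(extent_change_rate(r[1], r[2]),
                 -extent_change_rate(r[2], r[1]))
  }
})

test_that("local margin temperature change uses all period years", {
  yrs <- c(1984:1988, 2002:2006)
  warm43 <- make_grid(lat = seq(39, 41, 0.25), lon = seq(-91, -89, 0.25),
                      years = yrs,
                      fill = function(la, lo, y, m) 12 + 0.43 * (y > 2000))
  m <- mk_margin(c(40, 40.3))
  expect_equal(local_margin_temperature_change(m, warm43, p1, p2), 0.43)

  flat <- make_grid(lat = seq(39, 41, 0.25), lon = seq(-91, -89, 0.25),
                    years = yrs, fill = 12)
  expect_equal(local_margin_temperature_change(m, flat, p1, p2), 0)

  # two routes warming by +0.2 and +0.6 -> mean +0.4
  two <- make_grid(lat = c(40, 44), lon = seq(-91, -89, 0.25), years = yrs,
                   fill = function(la, lo, y, m)
                     12 + (y > 2000) * ifelse(la < 42, 0.2, 0.6))
  m2 <- mk_margin(c(40, 44))
  expect_equal(local_margin_temperature_change(m2, two, p1, p2), 0.4)
})

test_that("shift outcomes are coded from the sign table and depend only on signs", {
  expect_equal(code_shift_outcome(12, 0.5)$outcome, 1L)
  expect_equal(code_shift_outcome(-12, 0.5)$outcome, 0L)
  expect_equal(code_shift_outcome(-12, -0.3)$outcome, 1L)
  expect_equal(code_shift_outcome(12, -0.3)$outcome, 0L)
  expect_equal(code_shift_outcome(0, 0.5)$outcome, 0L)  # no shift never matches
  z <- code_shift_outcome(5, 0)
  expect_equal(z$expected_direction, "poleward")
  expect_true(z$zero_delta_T)

  set.seed(8)
  for (i in 1:50) {
    d <- rnorm(1); dt <- rnorm(1)
    base <- code_shift_outcome(d, dt)
    scaled <- code_shift_outcome(d * runif(1, 0.01, 100),
                                 dt * runif(1, 0.01, 100))
    expect_equal(base$outcome, scaled$outcome)
    expect_equal(base$expected_direction, scaled$expected_direction)
  }
})

test_that("margin-limit regression recovers exact linear relationships", {
  x <- seq(-4, 4, length.out = 12)
  f1 <- margin_limit_regression(x, x)
  expect_equal(unname(f1$estimates["slope"]), 1)
  expect_equal(f1$r.squared, 1)
  # a constant offset models a persistent poleward gap: slope 1, intercept
  f2 <- margin_limit_regression(x, x + 2.5)
  expect_equal(unname(f2$estimates["slope"]), 1)
  expect_equal(unname(f2$estimates["intercept"]), 2.5)
  expect_equal(abs(f2$extras$slope_vs_one_t), 0, tolerance = 1e-8)
  expect_error(margin_limit_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(margin_limit_regression(1:2, 1:2), "at least 3")
})

test_that("the slope CI covers a known generating slope at nominal rate", {
  set.seed(101)
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(100)
    y <- 0.3 + 0.7 * x + rnorm(100, sd = 0.5)
    ci <- margin_limit_regression(x, y)$extras$slope_ci
    if (ci[1] <= 0.7 && 0.7 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("paired mean-difference test matches the hand t formula and handles degeneracy", {
  a <- c(3, 5, 9); b <- c(2, 3, 6)  # differences 1, 2, 3
  f <- paired_mean_difference_test(a, b)
  expect_equal(f$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(f$df, 2)

  same <- paired_mean_difference_test(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shift <- paired_mean_difference_test(1:5 + 2, 1:5)
  expect_true(is.infinite(shift$statistic))
  expect_true(shift$extras$degenerate)
  expect_error(paired_mean_difference_test(1, 1), "n >= 2")
  expect_error(paired_mean_difference_test(1:3, 1:4), "paired")
})

test_that("temporal gap regression reports persistence and systematic change", {
  gaps <- c(0.5, 1.2, 2.0, 2.7, 3.1, 0.9, 1.8)
  f <- temporal_gap_regression(gaps, gaps)
  expect_equal(unname(f$estimates["slope"]), 1)
  expect_equal(f$extras$paired$statistic, 0)

  g <- temporal_gap_regression(gaps, gaps + 1)
  expect_equal(unname(g$estimates["intercept"]), 1)
  expect_equal(unname(g$estimates["slope"]), 1)
  expect_true(is.infinite(g$extras$paired$statistic))
  expect_true(g$extras$paired$extras$degenerate)
})

test_that("the logistic shift-probability model fits, flags separation, and degrades gracefully", {
  dat <- simulate_proximity_outcomes(n = 60, seed = 4)
  f <- shift_probability_model(dat$distance, dat$outcome)
  expect_lt(unname(f$estimates["slope"]), 0)
  expect_false(f$extras$separation)
  expect_true(f$p.value >= 0 && f$p.value <= 1)

  const <- shift_probability_model(rep(2, 20), rep(c(0, 1), 10))
  expect_equal(unname(const$estimates["slope"]), 0)
  expect_equal(const$p.value, 1)

  # perfectly separated toy input
  x <- c(1:6, 7:12)
  y <- c(rep(1, 6), rep(0, 6))
  sep <- shift_probability_model(x, y)
  expect_true(sep$extras$separation)
  expect_lt(unname(sep$estimates["slope"]), 0)

  expect_error(shift_probability_model(1:5, c(0, 1, 0, 1, 0)), "n >= 10")
  expect_error(shift_probability_model(1:10, rep(1, 10)), "both outcome")
})

test_that("OLS and logistic fits agree with independent oracles to 6 significant figures", {
  set.seed(400)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    y <- 0.5 - 0.8 * x + rnorm(n)
    f <- margin_limit_regression(x, y)
    o <- ref_ols(x, y)
    expect_equal(unname(f$estimates["slope"]), o$slope, tolerance = 1e-7)
    expect_equal(unname(f$estimates["intercept"]), o$intercept,
                 tolerance = 1e-7)
    expect_equal(f$r.squared, o$r.squared, tolerance = 1e-7)

    yb <- rbinom(n, 1, plogis(0.3 + 0.9 * x))
    if (length(unique(yb)) < 2) next
    fl <- shift_probability_model(x, yb)
    if (fl$extras$separation) next
    ol <- ref_logistic(x, yb)
    expect_equal(unname(fl$estimates["slope"]), ol$coef[2],
                 tolerance = 1e-6)
    expect_equal(fl$log_lik, ol$log_lik, tolerance = 1e-6)
  }
})

test_that("the full shift pipeline codes a tracked warming scenario as expected-direction shifts", {
  cfg <- tiny_cfg(warming = 1, seed = 5L)
  tr <- species_truth("spA", 7, 3, 9.5)
  g <- generate_climate(cfg)
  obs <- simulate_observations(cfg, tr, g)
  an <- analyze_range_shifts(obs, g, cfg$period1, cfg$period2)
  sh <- an$shifts
  expect_equal(nrow(sh), 2)
  expect_true(all(sh$expected_direction == "poleward"))
  expect_equal(sh$delta_T_margin, c(1, 1), tolerance = 1e-9)
  # both margins thermally limited: both track poleward
  expect_true(all(sh$outcome == 1L))
  expect_lt(max(abs(sh$displacement_km - 111.195)), 30)
})
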