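#' Between-period displacement of a range margin
#'
#' Converts the change in a margin set's mean latitude between two periods
#' into kilometers along the meridian (111.195 km per degree on a spherical
#' Earth). Positive values are poleward displacement for both margin sides.
#'
#' @param margin_t1,margin_t2 [margin_route_set()]s for the same species
#'   and side in the historical and later periods.
#' @return Signed displacement in km (poleward positive).
#' @export
margin_displacement_km <- function(margin_t1, margin_t2) {
  stopifnot(inherits(margin_t1, "margin_set"),
            inherits(margin_t2, "margin_set"))
  if (!identical(margin_t1$species_id, margin_t2$species_id))
    stop("margin_displacement_km: margins are for different species")
  if (!identical(margin_t1$side, margin_t2$side))
    stop("margin_displacement_km: margins are for different sides")
  (margin_t2$mean_latitude - margin_t1$mean_latitude) * KM_PER_DEGREE_LAT
}

#' Scale a displacement to a per-decade rate
#'
#' Divides the between-period displacement by the gap between the two
#' period midpoints and rescales to a decade. For the default 1984-1988 vs
#' 2002-2006 windows the midpoint gap is 18 years.
#'
#' @param displacement_km Signed displacement in km.
#' @param period1,period2 The two [period_window()]s (must be disjoint in
#'   midpoint).
#' @return Rate in km/decade (poleward positive).
#' @export
per_decade_rate <- function(displacement_km, period1, period2) {
  gap <- period_midpoint(period2) - period_midpoint(period1)
  if (gap == 0) stop("per_decade_rate: periods have identical midpoints")
  displacement_km * 10 / gap
}

#' Net change in latitudinal range extent
#'
#' Combines poleward-positive shift rates at the two margins into a net
#' extent change: `poleward_rate - equatorward_rate`. Negative values mean
#' the range is contracting (the equatorward margin is moving poleward
#' faster than the poleward margin is).
#'
#' @param poleward_rate,equatorward_rate Rates in km/decade, poleward
#'   positive at both margins.
#' @return Net extent change in km/decade.
#' @export
extent_change_rate <- function(poleward_rate, equatorward_rate) {
  poleward_rate - equatorward_rate
}

# per-route all-years temperature change between two periods, for the
# member routes of a margin/limit set (not observation-year conditional:
# the species may be absent in period 2)
.route_period_delta_T <- function(members, grid, period1, period2,
                                  buffer_km = 20, months = c(4L, 5L, 6L)) {
  routes <- members[, c("route_id", "latitude", "longitude")]
  y1 <- period_years(period1); y2 <- period_years(period2)
  tm <- route_breeding_temps(grid, routes, c(y1, y2),
                             buffer_km = buffer_km, months = months)
  rowMeans(tm[, as.character(y2), drop = FALSE]) -
    rowMeans(tm[, as.character(y1), drop = FALSE])
}

#' Local temperature change on the historical range margin
#'
#' Mean, over the historical margin routes, of the difference in mean
#' breeding-season temperature between the two periods, using all years of
#' each period rather than observation years only -- the species may be
#' locally extinct in the later period, and the predictor of that outcome
#' cannot condition on presence.
#'
#' @param margin_t1 Historical-period [margin_route_set()].
#' @param grid A [temp_grid()] covering both periods at the margin routes.
#' @param period1,period2 The two [period_window()]s.
#' @inheritParams breeding_season_temperature
#' @return Mean temperature change in degrees C (warming positive).
#' @export
local_margin_temperature_change <- function(margin_t1, grid, period1, period2,
                                            buffer_km = 20,
                                            months = c(4L, 5L, 6L)) {
  stopifnot(inherits(margin_t1, "margin_set"))
  mean(.route_period_delta_T(margin_t1$members, grid, period1, period2,
                             buffer_km = buffer_km, months = months))
}

#' Code a margin shift against its climatically expected direction
#'
#' Warming at the historical margin leads us to expect poleward movement
#' (colonization beyond the poleward edge, losses at the equatorward edge);
#' cooling the opposite. The binary outcome is 1 when the observed
#' displacement sign matches the expectation and 0 otherwise; zero
#' displacement never matches. Zero temperature change is coded
#' expected-poleward by convention and flagged. Both inputs enter through
#' their signs only.
#'
#' @param displacement_km Signed displacement (poleward positive);
#'   vectorized.
#' @param delta_T_margin Temperature change at the historical margin
#'   (degrees C); vectorized.
#' @return Data frame with columns `expected_direction`, `outcome` (0/1)
#'   and `zero_delta_T` (flag for the tie-break convention).
#' @export
code_shift_outcome <- function(displacement_km, delta_T_margin) {
  stopifnot(all(is.finite(delta_T_margin)))
  n <- max(length(displacement_km), length(delta_T_margin))
  displacement_km <- rep_len(displacement_km, n)
  delta_T_margin <- rep_len(delta_T_margin, n)
  expected <- ifelse(delta_T_margin >= 0, "poleward", "equatorward")
  matched <- (expected == "poleward" & displacement_km > 0) |
    (expected == "equatorward" & displacement_km < 0)
  data.frame(
    expected_direction = expected,
    outcome = as.integer(matched),
    zero_delta_T = delta_T_margin == 0,
    stringsAsFactors = FALSE
  )
}

# shared OLS machinery for the two regression wrappers
.ols_fit <- function(x, y, method) {
  if (length(x) != length(y)) stop(method, ": x and y lengths differ")
  n <- length(x)
  if (n < 3) stop(method, ": need at least 3 species")
  if (stats::var(x) == 0) stop(method, ": zero variance in x")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on (legitimate) exactly-linear inputs
  s <- suppressWarnings(summary(fit))
  if (stats::var(y) == 0) s$r.squared <- 0
  b <- stats::coef(fit)
  se <- s$coefficients[, "Std. Error"]
  slope_p <- s$coefficients["x", "Pr(>|t|)"]
  # departure of the slope from the 1:1 reference line
  t_one <- (b[["x"]] - 1) / se[["x"]]
  p_one <- 2 * stats::pt(-abs(t_one), df = n - 2)
  tcrit <- stats::qt(0.975, df = n - 2)
  fit_result(
    method = method,
    estimates = c(intercept = unname(b[1]), slope = unname(b[2])),
    se = c(intercept = unname(se[1]), slope = unname(se[2])),
    statistic = unname(s$coefficients["x", "t value"]),
    df = n - 2,
    p.value = slope_p,
    r.squared = s$r.squared,
    n = n,
    extras = list(
      slope_ci = unname(b[["x"]] + c(-1, 1) * tcrit * se[["x"]]),
      slope_vs_one_t = unname(t_one),
      slope_vs_one_p = unname(p_one)
    )
  )
}

#' Regress margin temperatures on thermal-limit temperatures
#'
#' Ordinary least-squares fit of per-species (breadth-adjusted) range
#' margin temperature on the corresponding (breadth-adjusted) thermal
#' niche limit temperature. Under perfect correspondence between margins
#' and realized limits the points fall on the 1:1 line; a constant
#' poleward gap appears as slope 1 with a positive intercept. The result
#' carries the slope's two-sided p-value, its 95% CI, and a test of
#' departure from slope 1.
#'
#' @param x Per-species limit temperatures (predictor).
#' @param y Per-species margin temperatures (response).
#' @return A [fit_result()].
#' @export
margin_limit_regression <- function(x, y) {
  .ols_fit(x, y, "margin_limit_regression")
}

#' Paired t-test of two per-species measurements
#'
#' Two-sided paired t-test on per-species differences `a - b` with
#' `df = n - 1`. Degenerate zero-variance differences do not error: equal
#' vectors give t = 0, p = 1, and a constant nonzero difference is
#' reported as an infinite t with the `degenerate` flag set.
#'
#' @param a,b Numeric vectors of equal length, paired by species.
#' @return A [fit_result()] with the mean difference as estimate.
#' @export
paired_mean_difference_test <- function(a, b) {
  if (length(a) != length(b))
    stop("paired_mean_difference_test: inputs must be paired (equal length)")
  n <- length(a)
  if (n < 2) stop("paired_mean_difference_test: need n >= 2 pairs")
  d <- a - b
  # sd exactly 0 or within rounding of it (t.test would refuse the latter)
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    md <- mean(d)
    stat <- if (md == 0) 0 else sign(md) * Inf
    return(fit_result(
      method = "paired_t",
      estimates = c(mean_difference = md),
      statistic = stat, df = n - 1,
      p.value = if (md == 0) 1 else 0,
      n = n, extras = list(degenerate = TRUE)
    ))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  fit_result(
    method = "paired_t",
    estimates = c(mean_difference = unname(tt$estimate)),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n = n,
    extras = list(degenerate = FALSE, conf_int = as.numeric(tt$conf.int))
  )
}

#' Temporal regression of environmental-distance gaps
#'
#' Tests whether the temperature gap between a range margin and its
#' thermal-niche limit changed between periods: OLS of later-period gaps
#' on historical gaps (slope 1, intercept 0 under perfect persistence)
#' together with a paired t-test of the mean gap change, returned under
#' `extras$paired`.
#'
#' @param gap_t1,gap_t2 Per-species environmental distances (degrees C) in
#'   the historical and later periods.
#' @return A [fit_result()] (the OLS fit, with the paired test attached).
#' @export
temporal_gap_regression <- function(gap_t1, gap_t2) {
  res <- .ols_fit(gap_t1, gap_t2, "temporal_gap_regression")
  res$extras$paired <- paired_mean_difference_test(gap_t2, gap_t1)
  res
}

# Firth-penalized logistic regression (Jeffreys prior) via IRLS with the
# hat-diagonal score correction; used when ML estimates do not exist
# because of complete or quasi-complete separation.
.firth_logistic <- function(x, y, max_iter = 200L, tol = 1e-10) {
  X <- unname(cbind(1, x))
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XWX <- crossprod(X * w, X)
    XWXi <- solve(XWX)
    h <- rowSums((X %*% XWXi) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(XWXi %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  XWX <- crossprod(X * w, X)
  loglik <- sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(XWX)$modulus
  beta <- unname(beta)
  list(coef = c(intercept = beta[1], slope = beta[2]),
       vcov = solve(XWX), log_lik = as.numeric(loglik))
}

.firth_null <- function(y, max_iter = 200L, tol = 1e-12) {
  # intercept-only Firth fit, for the penalized likelihood-ratio test
  b <- 0
  n <- length(y)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(b)
    w <- n * p * (1 - p)
    # hat diagonals are all 1/n here, so the score correction is (0.5 - p)
    U <- sum(y - p) + (0.5 - p)
    step <- U / w
    b <- b + step
    if (abs(step) < tol) break
  }
  eta <- rep(b, n)
  p <- stats::plogis(b)
  sum(y * eta - log1p(exp(eta))) + 0.5 * log(n * p * (1 - p))
}

#' Logistic model of shift probability on thermal proximity
#'
#' Maximum-likelihood logistic regression of the binary shift outcome
#' (1 = margin moved in the climatically expected direction) on the
#' species' historical environmental distance between margin and thermal
#' limit. A negative proximity coefficient means shifts in the expected
#' direction -- for equatorward margins, marginal-population extinctions --
#' become more likely as the margin approaches the realized thermal limit.
#' Significance is a likelihood-ratio test against the intercept-only
#' model. Complete or quasi-complete separation is detected and the fit
#' falls back to Firth penalized likelihood with the `separation` flag set.
#'
#' @param proximity Per-species environmental distance (degrees C) at the
#'   historical margin.
#' @param outcome 0/1 outcome vector.
#' @return A [fit_result()] with coefficient estimates, the model
#'   log-likelihood, and the likelihood-ratio p-value.
#' @export
shift_probability_model <- function(proximity, outcome) {
  if (length(proximity) != length(outcome))
    stop("shift_probability_model: inputs must have equal length")
  n <- length(outcome)
  if (n < 10) stop("shift_probability_model: need n >= 10 species")
  if (!all(outcome %in% c(0, 1)))
    stop("shift_probability_model: outcome must be 0/1")
  if (length(unique(outcome)) < 2)
    stop("shift_probability_model: both outcome classes must be present")
  if (stats::var(proximity) == 0) {
    # no thermal-proximity information: slope 0 by convention, LR test null
    p0 <- mean(outcome)
    ll <- sum(outcome * log(p0) + (1 - outcome) * log(1 - p0))
    return(fit_result(
      method = "logistic_shift_probability",
      estimates = c(intercept = stats::qlogis(p0), slope = 0),
      statistic = 0, df = 1, p.value = 1, log_lik = ll, n = n,
      extras = list(separation = FALSE, constant_predictor = TRUE)
    ))
  }

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ proximity, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  p_hat <- fit$fitted.values
  separated <- sep_warn || any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8) ||
    abs(stats::coef(fit)[2]) > 50

  if (separated) {
    ff <- .firth_logistic(proximity, outcome)
    ll0 <- .firth_null(outcome)
    lr <- 2 * (ff$log_lik - ll0)
    se <- sqrt(diag(ff$vcov))
    return(fit_result(
      method = "logistic_shift_probability (Firth)",
      estimates = ff$coef,
      se = c(intercept = se[1], slope = se[2]),
      statistic = max(lr, 0), df = 1,
      p.value = stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE),
      log_lik = ff$log_lik, n = n,
      extras = list(separation = TRUE)
    ))
  }

  s <- summary(fit)
  b <- stats::coef(fit)
  se <- s$coefficients[, "Std. Error"]
  lr <- fit$null.deviance - fit$deviance
  fit_result(
    method = "logistic_shift_probability",
    estimates = c(intercept = unname(b[1]), slope = unname(b[2])),
    se = c(intercept = unname(se[1]), slope = unname(se[2])),
    statistic = lr, df = 1,
    p.value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    log_lik = as.numeric(stats::logLik(fit)), n = n,
    extras = list(separation = FALSE,
                  z = unname(s$coefficients["proximity", "z value"]))
  )
}
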