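# Independent oracles used to cross-check the package's implementations.
# These are deliberately written with different algorithms from the code
# under test (repeated-scan selection instead of a vectorized sort; normal
# equations instead of lm; hand Newton-Raphson instead of glm).

# top-k route ids by repeated extraction of the extreme value, ties by
# smallest route_id
ref_topk_routes <- function(df, key, desc = FALSE, k = 10) {
  remaining <- df
  picked <- character()
  for (i in seq_len(min(k, nrow(df)))) {
    v <- remaining[[key]]
    best <- if (desc) max(v) else min(v)
    cand <- sort(remaining$route_id[v == best])
    picked <- c(picked, cand[1])
    remaining <- remaining[remaining$route_id != cand[1], , drop = FALSE]
  }
  picked
}

ref_weighted_mean <- function(temps, counts) {
  total <- 0
  wsum <- 0
  for (i in seq_along(temps)) {
    total <- total + temps[i] * counts[i]
    wsum <- wsum + counts[i]
  }
  total / wsum
}

# OLS by the normal equations, with classical standard errors
ref_ols <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  tss <- sum((y - mean(y))^2)
  list(intercept = b[1], slope = b[2], se = se,
       r.squared = 1 - sum(res^2) / tss)
}

# logistic ML fit by plain Newton-Raphson
ref_logistic <- function(x, y, iters = 60) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(iters)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    beta <- beta + solve(t(X) %*% (X * W), t(X) %*% (y - p))
  }
  eta <- drop(X %*% beta)
  list(coef = unname(drop(beta)),
       log_lik = sum(y * eta - log(1 + exp(eta))))
}

# random single-species route-temperature table
random_route_temps <- function(n, species = "sp1", period = "historical",
                               lat_ties = FALSE, t_ties = FALSE) {
  lat <- round(runif(n, 30, 50), if (lat_ties) 0 else 4)
  tt <- round(runif(n, 5, 25), if (t_ties) 0 else 4)
  data.frame(
    species_id = species,
    route_id = sprintf("r%03d", sample.int(999, n)),
    latitude = lat,
    longitude = runif(n, -100, -80),
    period = period,
    mean_breeding_T = tt,
    n_years = sample(1:5, n, replace = TRUE),
    total_count = sample(1:30, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
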