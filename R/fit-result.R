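#' Container for regression and test output
#'
#' Light wrapper holding the quantities the analyses report: coefficient
#' estimates and standard errors, a test statistic with its degrees of
#' freedom, a p-value, and where applicable an R-squared or a model
#' log-likelihood, plus the number of species rows supplied.
#'
#' @param method Short label for the fitted model or test.
#' @param estimates Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors (optional).
#' @param statistic Test statistic (t, z, chi-square, ...).
#' @param df Degrees of freedom.
#' @param p.value Two-sided p-value.
#' @param r.squared Coefficient of determination (OLS fits).
#' @param log_lik Model log-likelihood (likelihood fits).
#' @param n Number of observations (species) used.
#' @param extras Named list of any additional quantities.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(method, estimates, se = NULL, statistic = NULL,
                       df = NULL, p.value = NULL, r.squared = NULL,
                       log_lik = NULL, n, extras = list()) {
  if (!is.null(p.value) && is.finite(p.value) &&
      (p.value < 0 || p.value > 1))
    stop("fit_result: p.value outside [0, 1]")
  structure(
    list(method = method, estimates = estimates, se = se,
         statistic = statistic, df = df, p.value = p.value,
         r.squared = r.squared, log_lik = log_lik, n = n,
         extras = extras),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (n = %d)\n", x$method, x$n))
  if (length(x$estimates)) {
    est <- format(signif(x$estimates, 5))
    if (!is.null(x$se)) {
      cat("  estimates:\n")
      for (nm in names(x$estimates))
        cat(sprintf("    %-12s %10s  (se %s)\n", nm, est[nm],
                    format(signif(x$se[nm], 4))))
    } else {
      cat("  estimates:", paste(names(x$estimates), est, sep = " = ",
                                collapse = ", "), "\n")
    }
  }
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
                x$statistic, format(x$df), x$p.value))
  if (!is.null(x$r.squared))
    cat(sprintf("  R-squared = %.4f\n", x$r.squared))
  if (!is.null(x$log_lik))
    cat(sprintf("  log-likelihood = %.3f\n", x$log_lik))
  flags <- x$extras[vapply(x$extras, isTRUE, logical(1))]
  if (length(flags))
    cat("  flags:", paste(names(flags), collapse = ", "), "\n")
  invisible(x)
}
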