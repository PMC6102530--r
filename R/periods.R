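#' Define an analysis time period
#'
#' A period is an inclusive window of calendar years over which survey
#' observations are pooled. The study design compares two disjoint windows
#' (a historical baseline and a later period); five-year windows are the
#' default design but any positive length is accepted.
#'
#' @param label Short name for the period (e.g. `"historical"`).
#' @param start_year,end_year First and last calendar year, inclusive.
#' @return An object of class `period_window`.
#' @examples
#' p1 <- period_window("historical", 1984, 1988)
#' p2 <- period_window("modern", 2002, 2006)
#' period_years(p1)
#' @export
period_window <- function(label, start_year, end_year) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || end_year < start_year)
    stop("period_window: end_year must be >= start_year")
  structure(
    list(label = label, start_year = start_year, end_year = end_year),
    class = "period_window"
  )
}

#' @rdname period_window
#' @param period A `period_window`.
#' @export
period_years <- function(period) {
  stopifnot(inherits(period, "period_window"))
  seq.int(period$start_year, period$end_year)
}

#' @rdname period_window
#' @export
period_midpoint <- function(period) {
  stopifnot(inherits(period, "period_window"))
  (period$start_year + period$end_year) / 2
}

#' @export
print.period_window <- function(x, ...) {
  cat(sprintf("<period_window> %s: %d-%d\n", x$label, x$start_year, x$end_year))
  invisible(x)
}

#' The study's default analysis periods
#'
#' Two five-year windows, 1984-1988 and 2002-2006, chosen so that the span
#' within a period is much shorter than the 18-year midpoint gap between
#' them.
#'
#' @return A list with elements `historical` and `modern`.
#' @export
default_periods <- function() {
  list(
    historical = period_window("historical", 1984L, 1988L),
    modern = period_window("modern", 2002L, 2006L)
  )
}
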