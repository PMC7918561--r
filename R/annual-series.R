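#' Annual time series
#'
#' Light container for one named yearly series: a label, a measurement unit,
#' the calendar year of the first observation, and the observed values
#' \eqn{x^{(0)}(k)}, k = 1..m. Gray models index time by k; calendar years are
#' labels only.
#'
#' @param values numeric vector of finite observations, length >= 1.
#' @param start_year integer calendar year of the first value.
#' @param name series label.
#' @param unit measurement unit label (free text).
#' @return an object of class `annual_series`.
#' @examples
#' annual_series(c(458.66, 502.59, 579.00), 2000, name = "THE",
#'               unit = "billion yuan")
#' @export
annual_series <- function(values, start_year, name = "x", unit = "") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an annual series needs at least one value", call. = FALSE)
  if (!all(is.finite(values)))
    stop(sprintf("series '%s' contains non-finite values", name), call. = FALSE)
  start_year <- as.integer(start_year)
  if (is.na(start_year)) stop("start_year must be an integer", call. = FALSE)
  structure(list(name = as.character(name), unit = as.character(unit),
                 start_year = start_year, values = values),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("Annual series '%s'%s: %d values, %d-%d\n", x$name,
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else "",
              length(x$values), x$start_year, end_year(x)))
  print(stats::setNames(x$values, series_years(x)))
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$values)

#' Calendar years covered by a series or panel
#' @param x an `annual_series` or `study_panel`.
#' @return integer vector of years.
#' @export
series_years <- function(x) {
  if (inherits(x, "study_panel")) return(series_years(x$reference))
  x$start_year + seq_along(x$values) - 1L
}

end_year <- function(x) x$start_year + length(x$values) - 1L

#' Restrict a series to a year window
#' @param series an `annual_series`.
#' @param start_year,end_year inclusive window bounds.
#' @return the restricted `annual_series`.
#' @export
series_window <- function(series, start_year, end_year) {
  yrs <- series_years(series)
  if (start_year < yrs[1] || end_year > yrs[length(yrs)] || start_year > end_year)
    stop(sprintf("window %d-%d outside series '%s' range %d-%d",
                 start_year, end_year, series$name, yrs[1], yrs[length(yrs)]),
         call. = FALSE)
  annual_series(series$values[yrs >= start_year & yrs <= end_year],
                start_year, name = series$name, unit = series$unit)
}

#' Year-aligned study panel
#'
#' A reference series (the system characteristic, e.g. total health
#' expenditure) together with an ordered set of driving-factor series, all
#' covering identical years. Factor order is fixed and preserved; in
#' multivariate gray models the driving parameter \eqn{b_i} is mapped to
#' factors in this order.
#'
#' @param reference `annual_series` for the dependent variable.
#' @param factors list of `annual_series` for the drivers (order preserved).
#' @return an object of class `study_panel`.
#' @export
study_panel <- function(reference, factors) {
  stopifnot(inherits(reference, "annual_series"))
  if (length(factors) < 1L) stop("at least one factor is required", call. = FALSE)
  for (f in factors) {
    stopifnot(inherits(f, "annual_series"))
    if (f$start_year != reference$start_year ||
        length(f$values) != length(reference$values))
      stop(sprintf("factor '%s' is not aligned with reference '%s' (%d-%d)",
                   f$name, reference$name, reference$start_year,
                   end_year(reference)), call. = FALSE)
  }
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  structure(list(reference = reference, factors = factors,
                 year_range = c(reference$start_year, end_year(reference))),
            class = "study_panel")
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf("Study panel: reference '%s' + %d factors, %d-%d (%d years)\n",
              x$reference$name, length(x$factors), x$year_range[1],
              x$year_range[2], length(x$reference$values)))
  cat("Factors:", paste(names(x$factors), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.study_panel <- function(x, ...) {
  out <- data.frame(year = series_years(x))
  out[[x$reference$name]] <- x$reference$values
  for (f in x$factors) out[[f$name]] <- f$values
  out
}

#' Restrict a panel to a year window
#' @param panel a `study_panel`.
#' @param start_year,end_year inclusive window bounds.
#' @return the restricted `study_panel`.
#' @export
panel_window <- function(panel, start_year, end_year) {
  study_panel(series_window(panel$reference, start_year, end_year),
              lapply(panel$factors, series_window, start_year, end_year))
}

#' Matrix of factor values (years x factors)
#' @param panel a `study_panel`.
#' @return numeric matrix, one column per factor in panel order.
#' @export
factor_matrix <- function(panel) {
  m <- vapply(panel$factors, `[[`, numeric(length(panel$reference$values)),
              "values")
  matrix(m, ncol = length(panel$factors),
         dimnames = list(NULL, names(panel$factors)))
}
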