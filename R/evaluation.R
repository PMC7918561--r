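#' Residual percentage
#'
#' \eqn{\varphi = 100 \cdot |actual - prediction| / actual}, the per-year
#' accuracy measure used throughout the train/test protocol.
#'
#' @param actual observed value(s), nonzero.
#' @param prediction predicted value(s).
#' @return residual percentage(s).
#' @export
residual_percent <- function(actual, prediction) {
  if (any(actual == 0))
    stop("residual percentage undefined for actual = 0", call. = FALSE)
  100 * abs(actual - prediction) / actual
}

#' Evaluate predictions under the train/test protocol
#'
#' Builds the per-year comparison of predictions against observations, with
#' the residual percentage \eqn{\varphi_i} per year, the training average
#' RE_1 (the anchored first training year, where the fitted value equals the
#' observation by construction, is excluded) and the test average RE_2
#' (unweighted means).
#'
#' @param predictions an [annual_series()] of fitted/predicted values
#'   covering all train and test years.
#' @param actual an [annual_series()] of observations covering the same
#'   years.
#' @param train_years inclusive `c(start, end)` training window.
#' @param test_years inclusive `c(start, end)` test window, or NULL for
#'   training-only evaluation.
#' @param model_name label recorded on the report.
#' @return a `gray_fit_report`: `rows` (year, actual, prediction, phi, set),
#'   `re_train`, `re_test`.
#' @examples
#' panel <- china_health_panel()
#' fit <- nsgm(panel, train_end = 2016)
#' evaluate(predict(fit, 2018), panel$reference,
#'          train_years = c(2000, 2016), test_years = c(2017, 2018))
#' @export
evaluate <- function(predictions, actual, train_years, test_years = NULL,
                     model_name = predictions$name) {
  years <- if (is.null(test_years)) train_years[1]:train_years[2]
           else c(train_years[1]:train_years[2],
                  test_years[1]:test_years[2])
  if (!is.null(test_years) && test_years[1] <= train_years[2])
    stop("test window must start after the training window", call. = FALSE)
  pick <- function(s, what) {
    yrs <- series_years(s)
    if (!all(years %in% yrs))
      stop(sprintf("%s series does not cover %d-%d", what, min(years),
                   max(years)), call. = FALSE)
    s$values[match(years, yrs)]
  }
  act <- pick(actual, "actual")
  pred <- pick(predictions, "prediction")
  phi <- residual_percent(act, pred)
  set <- ifelse(years <= train_years[2], "train", "test")
  phi[1] <- NA_real_  # anchored first training year
  rows <- data.frame(year = years, actual = act, prediction = pred,
                     phi = phi, set = set)
  structure(list(model_name = model_name, rows = rows,
                 train_years = train_years, test_years = test_years,
                 re_train = mean(phi[set == "train"], na.rm = TRUE),
                 re_test = if (is.null(test_years)) NA_real_
                           else mean(phi[set == "test"])),
            class = "gray_fit_report")
}

#' @export
print.gray_fit_report <- function(x, digits = 2, ...) {
  cat(sprintf("Fit report: %s (train %d-%d%s)\n", x$model_name,
              x$train_years[1], x$train_years[2],
              if (is.null(x$test_years)) "" else
                sprintf(", test %d-%d", x$test_years[1], x$test_years[2])))
  rows <- x$rows
  rows$prediction <- round(rows$prediction, digits)
  rows$phi <- round(rows$phi, digits)
  print(rows, row.names = FALSE)
  cat(sprintf("RE_1 (train) = %.2f%%", x$re_train))
  if (!is.na(x$re_test)) cat(sprintf("   RE_2 (test) = %.2f%%", x$re_test))
  cat("\n")
  invisible(x)
}

#' Endpoint growth statistics of a series
#'
#' Total growth and compound (geometric-mean) annual growth rate between two
#' calendar years: \eqn{100 (x_e/x_s - 1)} and
#' \eqn{100 ((x_e/x_s)^{1/(e-s)} - 1)} with the year difference as exponent
#' base.
#'
#' @param series an [annual_series()].
#' @param start_year,end_year endpoint years (defaults: series range).
#' @return list with `total_growth_pct` and `cagr_pct`.
#' @export
growth_stats <- function(series, start_year = NULL, end_year = NULL) {
  yrs <- series_years(series)
  if (is.null(start_year)) start_year <- yrs[1]
  if (is.null(end_year)) end_year <- yrs[length(yrs)]
  if (end_year <= start_year) stop("end_year must exceed start_year",
                                   call. = FALSE)
  v0 <- series$values[match(start_year, yrs)]
  v1 <- series$values[match(end_year, yrs)]
  if (is.na(v0) || is.na(v1)) stop("endpoint year outside series",
                                   call. = FALSE)
  if (v0 == 0) stop("zero start value: growth undefined", call. = FALSE)
  list(total_growth_pct = 100 * (v1 / v0 - 1),
       cagr_pct = 100 * ((v1 / v0)^(1 / (end_year - start_year)) - 1))
}

#' Growth elasticity of one series against another
#'
#' Ratio of compound annual growth rates over a window, e.g. the elasticity
#' of health consumption THE/GDP: a value above 1 means health spending
#' outpaces the economy.
#'
#' @param panel a [study_panel()].
#' @param numerator,denominator series names in the panel.
#' @param start_year,end_year window endpoints (defaults: panel range).
#' @return the elasticity (dimensionless).
#' @export
elasticity <- function(panel, numerator, denominator,
                       start_year = NULL, end_year = NULL) {
  get_series <- function(nm) {
    if (nm == panel$reference$name) panel$reference
    else if (nm %in% names(panel$factors)) panel$factors[[nm]]
    else stop(sprintf("no series '%s' in panel", nm), call. = FALSE)
  }
  num <- growth_stats(get_series(numerator), start_year, end_year)
  den <- growth_stats(get_series(denominator), start_year, end_year)
  num$cagr_pct / den$cagr_pct
}

#' Expenditure share
#'
#' Percentage one series represents of another in a given year (e.g.
#' out-of-pocket spending as a share of total health expenditure).
#'
#' @param panel a [study_panel()].
#' @param numerator,denominator series names in the panel.
#' @param year calendar year.
#' @return share in percent.
#' @export
expenditure_share <- function(panel, numerator, denominator, year) {
  df <- as.data.frame(panel)
  row <- match(year, df$year)
  if (is.na(row)) stop("year outside panel", call. = FALSE)
  for (nm in c(numerator, denominator))
    if (!nm %in% names(df)) stop(sprintf("no series '%s' in panel", nm),
                                 call. = FALSE)
  100 * df[[numerator]][row] / df[[denominator]][row]
}

#' Descriptive health-financing statistics of a panel
#'
#' Endpoint growth and compound annual growth for every series, per-year
#' financing shares (by default OOP/THE, GGHE/THE and THE/GDP when those
#' series are present), and the reference-vs-GDP growth elasticity over the
#' window.
#'
#' @param panel a [study_panel()].
#' @param start_year,end_year window endpoints (defaults: panel range).
#' @param share_pairs list of `c(numerator, denominator)` pairs; NULL picks
#'   the default financing shares available in the panel.
#' @return a `descriptive_stats` object: data.frames `growth` and `shares`,
#'   scalar `elasticity` (NA when no GDP series exists).
#' @export
descriptive_stats <- function(panel, start_year = NULL, end_year = NULL,
                              share_pairs = NULL) {
  yrs <- series_years(panel)
  if (is.null(start_year)) start_year <- yrs[1]
  if (is.null(end_year)) end_year <- yrs[length(yrs)]
  all_series <- c(list(panel$reference), unname(panel$factors))
  growth <- do.call(rbind, lapply(all_series, function(s) {
    g <- growth_stats(s, start_year, end_year)
    data.frame(series = s$name, total_growth_pct = g$total_growth_pct,
               cagr_pct = g$cagr_pct)
  }))
  nm <- c(panel$reference$name, names(panel$factors))
  if (is.null(share_pairs)) {
    ref <- panel$reference$name
    share_pairs <- Filter(function(p) all(p %in% nm),
                          list(c("OOP", ref), c("GGHE", ref), c(ref, "GDP")))
  }
  shares <- do.call(rbind, lapply(share_pairs, function(p) {
    data.frame(year = start_year:end_year, numerator = p[1],
               denominator = p[2],
               percent = vapply(start_year:end_year, function(y)
                 expenditure_share(panel, p[1], p[2], y), numeric(1)))
  }))
  el <- if ("GDP" %in% nm && panel$reference$name != "GDP")
    elasticity(panel, panel$reference$name, "GDP", start_year, end_year)
  else NA_real_
  structure(list(start_year = start_year, end_year = end_year,
                 growth = growth, shares = shares, elasticity = el),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("Descriptive statistics, %d-%d\n", x$start_year, x$end_year))
  g <- x$growth
  g$total_growth_pct <- round(g$total_growth_pct, 2)
  g$cagr_pct <- round(g$cagr_pct, 2)
  print(g, row.names = FALSE)
  if (!is.na(x$elasticity))
    cat(sprintf("Elasticity (%s vs GDP): %.2f\n",
                "reference CAGR ratio", x$elasticity))
  invisible(x)
}

#' Round half away from zero
#'
#' Rounding convention of printed statistical tables (base [round()] rounds
#' half to even); used when comparing computed values against published
#' figures.
#'
#' @param x numeric.
#' @param d decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, d = 0) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
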