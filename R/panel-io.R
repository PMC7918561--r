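#' Load an annual panel from a wide CSV
#'
#' The canonical on-disk format is wide: one `year` column plus one numeric
#' column per series (header row, UTF-8, no thousands separators). Years must
#' be consecutive; the column named by `reference_name` becomes the panel
#' reference and every remaining column a factor, in file order.
#'
#' @param path CSV file path.
#' @param reference_name column holding the dependent series (default "THE").
#' @param units optional named character vector of units per series.
#' @return a [study_panel()].
#' @seealso [china_health_panel()] for the built-in study fixture,
#'   [write_panel()] for the inverse.
#' @export
load_panel <- function(path, reference_name = "THE", units = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("panel CSV needs a year column and at least 2 series columns",
         call. = FALSE)
  ycol <- which(tolower(names(df)) == "year")
  if (length(ycol) != 1L)
    stop("panel CSV must have exactly one 'year' column", call. = FALSE)
  years <- df[[ycol]]
  if (!is.numeric(years) || any(years != as.integer(years)))
    stop("year column must hold integer years", call. = FALSE)
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L)) {
    gap <- which(diff(years) != 1L)[1]
    stop(sprintf("years must be consecutive: gap between %d and %d",
                 years[gap], years[gap + 1L]), call. = FALSE)
  }
  series_cols <- setdiff(names(df), names(df)[ycol])
  if (!reference_name %in% series_cols)
    stop(sprintf("reference column '%s' not found (columns: %s)",
                 reference_name, paste(series_cols, collapse = ", ")),
         call. = FALSE)
  mk <- function(nm) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   nm, bad, v[bad]), call. = FALSE)
    }
    annual_series(v, years[1], name = nm,
                  unit = if (!is.null(units) && nm %in% names(units))
                    units[[nm]] else "")
  }
  factors <- lapply(setdiff(series_cols, reference_name), mk)
  study_panel(mk(reference_name), factors)
}

#' Write a panel as a wide CSV
#'
#' Inverse of [load_panel()]: full-precision values, one column per series.
#'
#' @param panel a `study_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Units from the study table footnotes.
.china_units <- c(
  THE = "billion yuan", ABOVE65 = "million persons", POP = "million persons",
  GDP = "billion yuan", PER = "thousand persons", BED = "thousand beds",
  GGHE = "billion yuan", OOP = "billion yuan", INF = "per 1000 live births",
  HCE = "yuan per capita")

#' China total health expenditure panel, 2000-2018
#'
#' The built-in study fixture: annual total health expenditure (THE) for
#' China together with nine driving factors — population aged 65+
#' (ABOVE65), population (POP), gross domestic product (GDP), medical
#' technical personnel (PER), healthcare beds (BED), general government
#' health expenditure (GGHE), out-of-pocket expenditure (OOP), infant
#' mortality (INF) and household consumption expenditure (HCE) — for
#' 2000-2018, from the China Statistical Yearbook / China National Health
#' Accounts Report as compiled in the source study.
#'
#' @return a [study_panel()] with reference THE and the nine factors in the
#'   order above.
#' @examples
#' panel <- china_health_panel()
#' panel$reference$values[1]   # 458.66 billion yuan in 2000
#' @export
china_health_panel <- function() {
  path <- system.file("extdata", "china_the_2000_2018.csv",
                      package = "graysys", mustWork = TRUE)
  load_panel(path, reference_name = "THE", units = .china_units)
}

#' Serialize a fit report or GRA result
#'
#' Writes a [gray_fit_report][evaluate()] or [gra][gra()] result to CSV or
#' JSON at full numeric precision (display rounding happens only in print
#' methods). JSON fit reports use the schema
#' `{model, train_years, test_years, rows, re_train, re_test}` and round-trip
#' exactly; GRA CSV has one row per factor with columns name, degree, rank.
#'
#' @param report object returned by [evaluate()] or [gra()].
#' @param path output file path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "gray_fit_report")) {
    if (is.null(report$rows) || nrow(report$rows) == 0L)
      stop("empty fit report: nothing to write", call. = FALSE)
    if (format == "csv") {
      utils::write.csv(report$rows, path, row.names = FALSE)
    } else {
      rows <- report$rows
      names(rows)[names(rows) == "phi"] <- "residual_pct"
      jsonlite::write_json(
        list(model = report$model_name,
             train_years = report$train_years, test_years = report$test_years,
             rows = rows, re_train = report$re_train,
             re_test = report$re_test),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    }
  } else if (inherits(report, "gra_result")) {
    if (is.null(report$degrees) || length(report$degrees) == 0L)
      stop("GRA result has no degrees: run gra() first", call. = FALSE)
    tab <- data.frame(name = names(report$degrees),
                      degree = unname(report$degrees),
                      rank = unname(report$ranks))
    if (format == "csv") {
      utils::write.csv(tab, path, row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(xi = report$xi, delta_min = report$delta_min,
             delta_max = report$delta_max, factors = tab),
        path, auto_unbox = TRUE, digits = NA)
    }
  } else {
    stop("write_report() handles gray_fit_report and gra_result objects",
         call. = FALSE)
  }
  invisible(path)
}

#' Read back a JSON fit report
#' @param path file written by [write_report()] with `format = "json"`.
#' @return a `gray_fit_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(x$rows)
  names(rows)[names(rows) == "residual_pct"] <- "phi"
  structure(list(model_name = x$model, rows = rows,
                 train_years = x$train_years, test_years = x$test_years,
                 re_train = x$re_train, re_test = x$re_test),
            class = "gray_fit_report")
}
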