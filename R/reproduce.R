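#' One-shot reproduction of the study analysis
#'
#' Runs the complete pipeline on the built-in China 2000-2018 panel: gray
#' relational ranking of the nine driving factors over the full window, the
#' three forecasting models fitted on 2000-2016 and tested on 2017-2018,
#' and the descriptive financing statistics. Optionally writes
#' `gra_degrees.{csv,json}`, one fit report per model
#' (`{gm11,gmn,nsgm}_report.{csv,json}`), `parameters.json` and
#' `descriptive.json` to `output_dir`. Everything is deterministic: two runs
#' produce identical files.
#'
#' @param output_dir directory for report files, or NULL to skip writing.
#' @param train_end last training year (study protocol: 2016).
#' @param xi gray relational resolution coefficient.
#' @return invisible list with elements `gra`, `gm11`, `gmn`, `nsgm` (each
#'   model with its `fit` and `report`), and `stats`.
#' @export
reproduce_study <- function(output_dir = NULL, train_end = 2016, xi = 0.5) {
  panel <- china_health_panel()
  yrs <- series_years(panel)
  last <- yrs[length(yrs)]
  train <- c(yrs[1], train_end)
  test <- if (train_end < last) c(train_end + 1L, last) else NULL

  gra_res <- gra(panel, xi = xi)

  fit1 <- gm11(panel$reference, train_end = train_end)
  rep1 <- evaluate(predict(fit1, horizon = last - train_end),
                   panel$reference, train, test, model_name = "GM(1,1)")

  fitn <- gmn(panel, train_end = train_end)
  repn <- evaluate(predict(fitn, end_year = last), panel$reference, train,
                   test, model_name = sprintf("GM(1,%d)",
                                              length(fitn$b) + 1L))

  fits <- nsgm(panel, train_end = train_end)
  reps <- evaluate(predict(fits, end_year = last), panel$reference, train,
                   test, model_name = sprintf("NSGM(1,%d)",
                                              length(fits$b) + 1L))

  stats <- descriptive_stats(panel)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(output_dir, f)
    write_report(gra_res, p("gra_degrees.csv"), "csv")
    write_report(gra_res, p("gra_degrees.json"), "json")
    for (x in list(list("gm11", rep1), list("gmn", repn),
                   list("nsgm", reps))) {
      write_report(x[[2]], p(paste0(x[[1]], "_report.csv")), "csv")
      write_report(x[[2]], p(paste0(x[[1]], "_report.json")), "json")
    }
    jsonlite::write_json(
      list(gm11 = list(a = fit1$a, b = fit1$b),
           gmn = list(a = fitn$a, b = as.list(fitn$b)),
           nsgm = list(b = as.list(fits$b), a = fits$a, h1 = fits$h1,
                       h2 = fits$h2,
                       mu = c(fits$mu1, fits$mu2, fits$mu3, fits$mu4))),
      p("parameters.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(window = c(stats$start_year, stats$end_year),
           growth = stats$growth, shares = stats$shares,
           elasticity = stats$elasticity),
      p("descriptive.json"), auto_unbox = TRUE, digits = NA)
  }

  invisible(list(gra = gra_res,
                 gm11 = list(fit = fit1, report = rep1),
                 gmn = list(fit = fitn, report = repn),
                 nsgm = list(fit = fits, report = reps),
                 stats = stats))
}

#' Fit and evaluate one gray model on a panel
#'
#' Programmatic single-model entry point behind the command-line script:
#' fits the requested model on the training window, predicts through the end
#' of the test window using actual factor values, and returns (optionally
#' writes) the fit report.
#'
#' @param panel a [study_panel()] (e.g. from [load_panel()]).
#' @param model one of "gm11", "gmn", "nsgm".
#' @param train_years inclusive `c(start, end)` training window.
#' @param test_years inclusive `c(start, end)` test window, or NULL.
#' @param output optional report path.
#' @param format "csv" or "json" for `output`.
#' @return a `gray_fit_report` (invisibly if written).
#' @export
run_gray_model <- function(panel, model = c("nsgm", "gmn", "gm11"),
                           train_years, test_years = NULL, output = NULL,
                           format = c("csv", "json")) {
  model <- match.arg(model)
  yrs <- series_years(panel)
  if (train_years[1] != yrs[1])
    panel <- panel_window(panel, train_years[1], yrs[length(yrs)])
  end <- if (is.null(test_years)) train_years[2] else test_years[2]
  pred <- switch(model,
    gm11 = predict(gm11(panel$reference, train_end = train_years[2]),
                   horizon = end - train_years[2]),
    gmn = predict(gmn(panel, train_end = train_years[2]), end_year = end),
    nsgm = predict(nsgm(panel, train_end = train_years[2]), end_year = end))
  rep <- evaluate(pred, panel$reference, train_years, test_years,
                  model_name = model)
  if (!is.null(output)) {
    write_report(rep, output, match.arg(format))
    return(invisible(rep))
  }
  rep
}
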