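#' Mean-value normalization
#'
#' Dimensionless processing before gray relational analysis: each series is
#' divided by its own arithmetic mean, so the normalized values average to 1
#' and unit choices cancel.
#'
#' @param series an [annual_series()] or numeric vector.
#' @return numeric vector `x / mean(x)` (mean exactly 1).
#' @export
mean_normalize <- function(series) {
  v <- series_values(series)
  mu <- mean(v)
  if (abs(mu) < .Machine$double.eps * max(1, max(abs(v))))
    stop(sprintf("cannot mean-normalize '%s': series mean is zero",
                 series_label(series)), call. = FALSE)
  v / mu
}

#' Gray relational coefficients
#'
#' For each factor i and time point k, the relational coefficient compares
#' the gap \eqn{\Delta_i(k) = |x_0'(k) - x_i'(k)|} between the normalized
#' factor and reference trajectories against the global two-level extrema
#' \eqn{\Delta_{min}, \Delta_{max}} (over all factors and all k):
#' \deqn{\varepsilon_i(k) = \frac{\Delta_{min} + \xi\Delta_{max}}
#'                               {\Delta_i(k) + \xi\Delta_{max}}}
#' with resolution coefficient \eqn{\xi \in [0, 1]} (conventionally 0.5).
#' When every factor coincides with the reference (\eqn{\Delta_{max} = 0})
#' all coefficients are defined as 1.
#'
#' @param reference numeric vector: normalized reference trajectory.
#' @param factors list (or matrix columns) of normalized factor trajectories.
#' @param xi resolution coefficient in \[0, 1\].
#' @return a `gra_result` with `coefficients` (years x factors matrix),
#'   `delta_min`, `delta_max` and `xi`; degrees/ranks unset until
#'   [relational_degrees()].
#' @export
relational_coefficients <- function(reference, factors, xi = 0.5) {
  if (xi < 0 || xi > 1)
    stop("resolution coefficient xi must lie in [0, 1]", call. = FALSE)
  if (is.list(factors))
    factors <- vapply(factors, as.numeric, numeric(length(reference)))
  factors <- as.matrix(factors)
  if (nrow(factors) != length(reference))
    stop("reference and factor series must have equal length", call. = FALSE)
  delta <- abs(factors - reference)
  dmin <- min(delta)
  dmax <- max(delta)
  # normalized trajectories are O(1); a maximum gap at rounding-noise level
  # means every factor coincides with the reference
  eps <- if (dmax < 1e-12) array(1, dim(delta), dimnames = dimnames(delta))
         else (dmin + xi * dmax) / (delta + xi * dmax)
  structure(list(coefficients = eps, delta_min = dmin, delta_max = dmax,
                 xi = xi, degrees = NULL, ranks = NULL),
            class = "gra_result")
}

#' Gray relational degrees and ranking
#'
#' The degree of factor i is the time average of its relational coefficients,
#' \eqn{\beta_i = \frac{1}{m}\sum_k \varepsilon_i(k)}; ranks order the
#' degrees descending (rank 1 = most closely related to the reference), ties
#' broken by factor input order.
#'
#' @param result a `gra_result` from [relational_coefficients()].
#' @return the same object with `degrees` and `ranks` filled in.
#' @export
relational_degrees <- function(result) {
  stopifnot(inherits(result, "gra_result"))
  beta <- colMeans(result$coefficients)
  result$degrees <- beta
  result$ranks <- stats::setNames(
    match(seq_along(beta), order(-beta)), names(beta))
  result
}

#' Gray relational analysis of a study panel
#'
#' Ranks the driving factors of a panel by the similarity of their
#' mean-normalized trajectories to the reference series: normalization,
#' relational coefficients with global two-level extrema, then degrees and
#' ranks. Uses the panel's full year range.
#'
#' @param panel a [study_panel()].
#' @param xi resolution coefficient in \[0, 1\], default 0.5.
#' @return a `gra_result` with coefficients, extrema, degrees and ranks.
#' @examples
#' res <- gra(china_health_panel())
#' round(res$degrees, 3)   # GGHE 0.941 ranks first
#' @export
gra <- function(panel, xi = 0.5) {
  stopifnot(inherits(panel, "study_panel"))
  ref <- mean_normalize(panel$reference)
  facs <- lapply(panel$factors, mean_normalize)
  relational_degrees(relational_coefficients(ref, facs, xi = xi))
}

#' @export
print.gra_result <- function(x, digits = 3, ...) {
  cat(sprintf("Gray relational analysis (xi = %g)\n", x$xi))
  if (is.null(x$degrees)) {
    cat("coefficients only; run relational_degrees() for the ranking\n")
  } else {
    ord <- order(x$ranks)
    tab <- data.frame(factor = names(x$degrees)[ord],
                      degree = round(unname(x$degrees)[ord], digits),
                      rank = unname(x$ranks)[ord])
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
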