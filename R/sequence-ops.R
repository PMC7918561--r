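#' First-order accumulated generating operation (1-AGO)
#'
#' The cumulative-sum transform \eqn{x^{(1)}(k) = \sum_{j \le k} x^{(0)}(j)}
#' that regularizes a raw series before gray modelling: a noisy growth series
#' becomes a smooth, near-exponential accumulated curve.
#'
#' @param series an [annual_series()] (or bare numeric vector).
#' @return an `ago_series`: the accumulated values with the source name and
#'   start year attached.
#' @seealso [iago()] for the inverse, [background()] for mean-generated
#'   values.
#' @export
ago <- function(series) {
  v <- series_values(series)
  structure(list(source_name = series_label(series),
                 start_year = series_start(series),
                 values = cumsum(v)),
            class = "ago_series")
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First differencing with the first element preserved: maps an accumulated
#' sequence back to level scale, so `iago(ago(x))` is `x` to machine
#' precision.
#'
#' @param x an `ago_series` (or bare numeric vector).
#' @return an [annual_series()] on the original level scale.
#' @export
iago <- function(x) {
  v <- series_values(x)
  annual_series(c(v[1], diff(v)), series_start(x),
                name = series_label(x))
}

#' Background (mean-generated) values
#'
#' \eqn{z^{(1)}(k) = \frac{1}{2}[x^{(1)}(k) + x^{(1)}(k-1)]} for k = 2..m:
#' the trapezoidal discretization of the accumulated series that stands in
#' for the integral term of the whitening differential equation. The 1/2
#' coefficient is fixed (no generalized background weight).
#'
#' @param x an `ago_series` (or bare numeric vector of accumulated values).
#' @return numeric vector of length m - 1 (k = 2..m).
#' @export
background <- function(x) {
  v <- series_values(x)
  if (length(v) < 2L)
    stop("background values need at least 2 accumulated values",
         call. = FALSE)
  0.5 * (v[-1] + v[-length(v)])
}

#' @export
print.ago_series <- function(x, ...) {
  cat(sprintf("1-AGO of '%s' (%d values from %d)\n", x$source_name,
              length(x$values), x$start_year))
  print(x$values)
  invisible(x)
}

# Tolerant accessors so the operators also take bare numeric vectors.
series_values <- function(x) {
  if (is.numeric(x)) {
    if (length(x) < 1L) stop("empty series", call. = FALSE)
    return(as.numeric(x))
  }
  if (is.list(x) && !is.null(x$values)) return(x$values)
  stop("expected an annual_series, ago_series or numeric vector",
       call. = FALSE)
}
series_label <- function(x) if (is.numeric(x)) "x" else
  (x$name %||% x$source_name %||% "x")
series_start <- function(x) if (is.numeric(x)) 1L else (x$start_year %||% 1L)
`%||%` <- function(a, b) if (is.null(a)) b else a
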