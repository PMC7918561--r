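#' Fit a univariate gray model GM(1,1)
#'
#' Estimates the development parameter a and gray input b of the gray
#' difference equation
#' \deqn{x^{(0)}(k) + a z^{(1)}(k) = b, \quad k = 2..m,}
#' where \eqn{z^{(1)}} are the background values of the 1-AGO series, by
#' least squares on design rows \eqn{(-z^{(1)}(k), 1)} (solved by QR, never
#' explicit normal-equation inversion). A growing series yields a < 0.
#'
#' @param series an [annual_series()] with at least 4 values (the gray-model
#'   minimum sample size).
#' @param train_end optional last calendar year to fit on; default uses the
#'   whole series.
#' @return an object of class `gm11`: parameters `a`, `b`, the anchored
#'   initial value `x1_init`, training length `m_train`, and the design
#'   condition number `condition`.
#' @examples
#' the <- china_health_panel()$reference
#' fit <- gm11(the, train_end = 2016)
#' c(fit$a, fit$b)   # -0.147532, 430.168721
#' @export
gm11 <- function(series, train_end = NULL) {
  stopifnot(inherits(series, "annual_series"))
  if (!is.null(train_end))
    series <- series_window(series, series$start_year, train_end)
  x0 <- series$values
  m <- length(x0)
  if (m < 4L)
    stop("GM(1,1) needs at least 4 training values", call. = FALSE)
  z <- background(ago(series))
  B <- cbind(z = -z, const = 1)
  sol <- gray_ls_solve(B, x0[-1], context = "GM(1,1)")
  structure(list(a = unname(sol$coef[1]), b = unname(sol$coef[2]),
                 x1_init = x0[1], m_train = m,
                 start_year = series$start_year, series_name = series$name,
                 condition = sol$condition),
            class = "gm11")
}

#' Fitted values and forecasts from a GM(1,1) model
#'
#' Evaluates the exponential time response on the accumulated scale,
#' \deqn{\hat x^{(1)}(k+1) = \left(x^{(0)}(1) - \frac{b}{a}\right)e^{-ak}
#'       + \frac{b}{a},}
#' anchored at the observed first value, then maps back to level scale by
#' IAGO. For the degenerate a = 0 the response is linear,
#' \eqn{\hat x^{(1)}(k+1) = x^{(0)}(1) + bk}.
#'
#' @param object a fitted `gm11` model.
#' @param horizon number of years to forecast beyond the training window
#'   (default 0: fitted values only).
#' @param ... unused.
#' @return an [annual_series()] of `m_train + horizon` values starting at the
#'   first training year; the first value equals the observed initial value
#'   exactly.
#' @export
predict.gm11 <- function(object, horizon = 0, ...) {
  stopifnot(horizon >= 0)
  n <- object$m_train + horizon
  k <- seq_len(n) - 1
  x1hat <- if (abs(object$a) < 1e-12) {
    object$x1_init + object$b * k
  } else {
    (object$x1_init - object$b / object$a) * exp(-object$a * k) +
      object$b / object$a
  }
  x1hat[1] <- object$x1_init  # anchored exactly, free of rounding noise
  iag <- annual_series(c(x1hat[1], diff(x1hat)), object$start_year,
                       name = paste0(object$series_name, "_gm11"))
  iag
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("GM(1,1) on '%s' (%d years from %d)\n", x$series_name,
              x$m_train, x$start_year))
  cat(sprintf("  a = %.6f  b = %.6f  (design condition %.3g)\n",
              x$a, x$b, x$condition))
  invisible(x)
}
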