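#' Fit a traditional multivariate gray model GM(1,N)
#'
#' With reference series \eqn{x_1} and N-1 driving factors \eqn{x_2..x_N},
#' all accumulated by 1-AGO, the gray difference equation is
#' \deqn{x_1^{(0)}(k) + a z_1^{(1)}(k) = \sum_{i=2}^{N} b_{i-1}
#'       x_i^{(1)}(k), \quad k = 2..m.}
#' Parameters \eqn{(a, b_1, .., b_{N-1})} are estimated by least squares on
#' design rows \eqn{(-z_1^{(1)}(k), x_2^{(1)}(k), .., x_N^{(1)}(k))} via QR
#' (the system is ill-conditioned because accumulated factor columns grow in
#' near lockstep; the condition number is stored on the fit).
#'
#' @param panel a [study_panel()]; factor order fixes the order of `b`.
#' @param train_end last calendar year of the training window (default: the
#'   panel's last year). Later panel years are kept for out-of-sample
#'   prediction with actual factor values.
#' @return an object of class `gmn`: `a`, named vector `b`, `x1_init`,
#'   `m_train`, the full-panel factor AGO matrix `factor_ago`, and
#'   `condition`.
#' @examples
#' fit <- gmn(china_health_panel(), train_end = 2016)
#' round(fit$a, 4)
#' @export
gmn <- function(panel, train_end = NULL) {
  stopifnot(inherits(panel, "study_panel"))
  yrs <- series_years(panel)
  if (is.null(train_end)) train_end <- yrs[length(yrs)]
  m <- train_end - yrs[1] + 1L
  if (m < 4L) stop("GM(1,N) needs at least 4 training years", call. = FALSE)
  if (m > length(yrs)) stop("train_end beyond panel range", call. = FALSE)
  if (m - 1L < length(panel$factors) + 1L)
    stop(sprintf(paste("GM(1,%d) has %d parameters but only %d usable",
                       "training rows; need at least %d training years"),
                 length(panel$factors) + 1L, length(panel$factors) + 1L,
                 m - 1L, length(panel$factors) + 2L), call. = FALSE)

  x0 <- panel$reference$values[seq_len(m)]
  z <- background(cumsum(x0))
  fago <- apply(factor_matrix(panel), 2, cumsum)  # full range, all factors
  B <- cbind(-z, fago[2:m, , drop = FALSE])
  colnames(B) <- c("z1", colnames(fago))
  sol <- gray_ls_solve(B, x0[-1], context = "GM(1,N)")
  structure(list(a = unname(sol$coef[1]),
                 b = stats::setNames(sol$coef[-1], colnames(fago)),
                 x1_init = x0[1], m_train = m, factor_ago = fago,
                 start_year = yrs[1], end_year = yrs[length(yrs)],
                 series_name = panel$reference$name,
                 condition = sol$condition),
            class = "gmn")
}

#' Fitted values and predictions from a GM(1,N) model
#'
#' Uses the approximate time-corresponding formula: with the driving sum
#' \eqn{S(k) = \sum_i b_{i-1} x_i^{(1)}(k)} treated as constant over each
#' step,
#' \deqn{\hat x_1^{(1)}(k+1) = \left[x_1^{(0)}(1) - \frac{S(k+1)}{a}\right]
#'       e^{-ak} + \frac{S(k+1)}{a},}
#' then level-scale values by accumulated subtraction (IAGO). Test-year
#' predictions consume the actual factor values stored on the model, so the
#' panel passed to [gmn()] must cover every requested year.
#'
#' @param object a fitted `gmn` model.
#' @param end_year last calendar year to predict (default: last panel year).
#' @param ... unused.
#' @return an [annual_series()] from the first training year to `end_year`;
#'   the first value is the anchored observed initial value.
#' @export
predict.gmn <- function(object, end_year = NULL, ...) {
  if (abs(object$a) < 1e-12)
    stop("GM(1,N) time response is undefined for a = 0", call. = FALSE)
  if (is.null(end_year)) end_year <- object$end_year
  n <- end_year - object$start_year + 1L
  if (n < 1L || end_year > object$end_year)
    stop(sprintf("factor data available only for %d-%d", object$start_year,
                 object$end_year), call. = FALSE)
  S <- as.vector(object$factor_ago %*% object$b)
  x1hat <- numeric(n)
  x1hat[1] <- object$x1_init
  for (j in seq_len(n)[-1])
    x1hat[j] <- (object$x1_init - S[j] / object$a) * exp(-object$a * (j - 1)) +
      S[j] / object$a
  annual_series(c(x1hat[1], diff(x1hat)), object$start_year,
                name = paste0(object$series_name, "_gmn"))
}

#' @export
print.gmn <- function(x, ...) {
  cat(sprintf("GM(1,%d) on '%s' (%d training years from %d)\n",
              length(x$b) + 1L, x$series_name, x$m_train, x$start_year))
  cat(sprintf("  a = %.4f  (design condition %.3g)\n", x$a, x$condition))
  cat("  b:\n"); print(round(x$b, 4))
  invisible(x)
}
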