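#' Generate a GM(1,1)-consistent series
#'
#' Inverts the univariate gray difference equation: given parameters (a, b)
#' and initial value x1, builds the unique series with
#' \eqn{x^{(0)}(k) + a z^{(1)}(k) = b} holding exactly at every k, via the
#' recurrence \eqn{x^{(0)}(k) = (b - a x^{(1)}(k-1)) / (1 + a/2)}. Fitting
#' GM(1,1) to the output recovers (a, b) exactly (up to solver precision),
#' which makes this generator the parameter-recovery oracle.
#'
#' @param a development parameter (1 + a/2 must be nonzero).
#' @param b gray input.
#' @param x1 initial value \eqn{x^{(0)}(1)}.
#' @param m series length (>= 4).
#' @param start_year first calendar year label.
#' @param name series label.
#' @return an [annual_series()].
#' @export
gen_gm11_consistent <- function(a, b, x1, m, start_year = 2000,
                                name = "gm11_sim") {
  if (abs(1 + 0.5 * a) < 1e-12)
    stop("1 + a/2 = 0: recurrence undefined", call. = FALSE)
  if (m < 4L) stop("need m >= 4 for a fittable series", call. = FALSE)
  x0 <- numeric(m)
  x0[1] <- x1
  acc <- x1
  for (k in 2:m) {
    x0[k] <- (b - a * acc) / (1 + 0.5 * a)
    acc <- acc + x0[k]
  }
  annual_series(x0, start_year, name = name)
}

#' Generate an NSGM(1,N)-consistent panel
#'
#' Given driving parameters b, development parameter a, linear-correction
#' coefficient h1, gray action h2 and factor series, constructs the
#' reference series for which the NSGM gray difference equation holds
#' exactly at every step:
#' \deqn{x_1^{(0)}(k) = \frac{\sum_i b_i x_i^{(1)}(k) - a x_1^{(1)}(k-1)
#'       + h_1(k-1) + h_2}{1 + a/2}.}
#' Fitting [nsgm()] to the output recovers all parameters exactly. With
#' `h1 = h2 = 0` the construction degenerates to the GM(1,N) equation and is
#' exposed as [gen_gmn_consistent()].
#'
#' @param b numeric vector of driving parameters, one per factor.
#' @param a development parameter (1 + a/2 nonzero).
#' @param h1 linear-correction coefficient.
#' @param h2 gray action.
#' @param factors list of [annual_series()] (aligned, positive recommended).
#' @param x1 initial reference value.
#' @param name reference series label.
#' @return a [study_panel()] with the constructed reference and the supplied
#'   factors.
#' @export
gen_nsgm_consistent <- function(b, a, h1, h2, factors, x1,
                                name = "nsgm_sim") {
  if (abs(1 + 0.5 * a) < 1e-12)
    stop("1 + a/2 = 0: recurrence undefined", call. = FALSE)
  if (length(factors) != length(b))
    stop("need one driving parameter per factor", call. = FALSE)
  fmat <- vapply(factors, `[[`, numeric(length(factors[[1]]$values)),
                 "values")
  m <- nrow(fmat)
  fago <- apply(fmat, 2, cumsum)
  S <- as.vector(fago %*% b)
  x0 <- numeric(m)
  x0[1] <- x1
  acc <- x1
  for (k in 2:m) {
    x0[k] <- (S[k] - a * acc + h1 * (k - 1) + h2) / (1 + 0.5 * a)
    acc <- acc + x0[k]
  }
  study_panel(annual_series(x0, factors[[1]]$start_year, name = name),
              factors)
}

#' Generate a GM(1,N)-consistent panel
#'
#' [gen_nsgm_consistent()] with `h1 = h2 = 0`: the reference satisfies the
#' traditional GM(1,N) gray difference equation exactly, so [gmn()] recovers
#' `(a, b)` exactly.
#'
#' @inheritParams gen_nsgm_consistent
#' @return a [study_panel()].
#' @export
gen_gmn_consistent <- function(b, a, factors, x1, name = "gmn_sim") {
  gen_nsgm_consistent(b, a, h1 = 0, h2 = 0, factors = factors, x1 = x1,
                      name = name)
}

#' Generate a noisy near-exponential growth panel
#'
#' Emulates the statistical shape of the study panel: strictly positive
#' factor series growing at stated compound rates with multiplicative
#' lognormal noise, and a reference that is a positive linear combination of
#' the factors with its own multiplicative noise. Multiplicative lognormal
#' noise keeps every series positive, preserving AGO monotonicity and
#' mean-normalizability. Defaults mirror the study panel: 19 years, 9
#' factors, compound growth rates spread over 4-15% per year, 5% noise.
#'
#' All randomness is confined to this function and controlled by `seed`.
#'
#' @param m years (>= 4).
#' @param n_factors number of driving factors.
#' @param growth_rates per-factor compound annual growth rates (recycled).
#' @param base per-factor initial levels (recycled).
#' @param weights positive weights of the reference combination (recycled).
#' @param noise_sd lognormal sigma of the multiplicative noise (>= 0).
#' @param seed integer seed; same seed, same panel.
#' @param start_year first calendar year label.
#' @return a [study_panel()] with reference "REF" and factors "F1"..
#' @export
gen_noisy_growth <- function(m = 19, n_factors = 9,
                             growth_rates = seq(0.04, 0.15,
                                                length.out = n_factors),
                             base = 10^seq(2, 4, length.out = n_factors),
                             weights = rep(1, n_factors),
                             noise_sd = 0.05, seed = 1, start_year = 2000) {
  if (m < 4L) stop("need m >= 4", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  growth_rates <- rep_len(growth_rates, n_factors)
  base <- rep_len(base, n_factors)
  weights <- rep_len(weights, n_factors)
  set.seed(seed)
  k <- seq_len(m) - 1
  factors <- lapply(seq_len(n_factors), function(i) {
    noise <- if (noise_sd > 0) stats::rlnorm(m, 0, noise_sd) else rep(1, m)
    annual_series(base[i] * (1 + growth_rates[i])^k * noise, start_year,
                  name = paste0("F", i))
  })
  fmat <- vapply(factors, `[[`, numeric(m), "values")
  ref_noise <- if (noise_sd > 0) stats::rlnorm(m, 0, noise_sd) else rep(1, m)
  ref <- annual_series(as.vector(fmat %*% weights) * ref_noise, start_year,
                       name = "REF")
  study_panel(ref, factors)
}
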