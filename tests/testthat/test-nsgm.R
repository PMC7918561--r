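test_that("nsgm recovers parameters and reproduces consistent data exactly", {
  facs <- make_factors(n_factors = 2, m = 9)
  pan <- gen_nsgm_consistent(b = c(0.3, -0.2), a = 0.15, h1 = 2, h2 = 7,
                             factors = facs, x1 = 12)
  fit <- nsgm(pan)
  expect_equal(unname(fit$b), c(0.3, -0.2), tolerance = 1e-9)
  expect_equal(fit$a, 0.15, tolerance = 1e-9)
  expect_equal(fit$h1, 2, tolerance = 1e-9)
  expect_equal(fit$h2, 7, tolerance = 1e-9)
  # homology: the fitted one-step path reproduces the training data to
  # machine precision — the model's defining property
  expect_equal(predict(fit)$values, pan$reference$values,
               tolerance = 1e-12)
})

test_that("mu coefficients derive from a, h1, h2", {
  fit <- nsgm(china, train_end = 2016)
  expect_equal(fit$mu1, 1 / (1 + 0.5 * fit$a))
  expect_equal(fit$mu2, (1 - 0.5 * fit$a) / (1 + 0.5 * fit$a))
  expect_equal(fit$mu3, fit$h1 / (1 + 0.5 * fit$a))
  expect_equal(fit$mu4, (fit$h2 - fit$h1) / (1 + 0.5 * fit$a))
})

test_that("closed-form response equals the iterated recurrence", {
  # on the study fit
  chk <- nsgm_recurrence_check(nsgm(china, train_end = 2016))
  expect_lt(max(abs(chk$diff) / abs(chk$recurrence)), 1e-6)

  # property: random parameter sets, random factors
  set.seed(31)
  for (i in 1:25) {
    nf <- sample(1:3, 1)
    m <- sample((nf + 4):12, 1)
    facs <- random_factors(nf, m)
    pan <- gen_nsgm_consistent(b = runif(nf, -1, 1), a = runif(1, -0.8, 0.8),
                               h1 = runif(1, -5, 5), h2 = runif(1, -5, 5),
                               factors = facs, x1 = runif(1, 1, 10))
    chk <- nsgm_recurrence_check(nsgm(pan))
    expect_lt(max(abs(chk$diff)), 1e-8 * max(1, max(abs(chk$recurrence))))
  }
})

test_that("with h1 = h2 = 0 the recurrence reduces to GM(1,N)", {
  facs <- make_factors(2, 9)
  pan <- gen_gmn_consistent(b = c(0.4, 0.9), a = 0.25, factors = facs,
                            x1 = 6)
  fit <- nsgm(pan)
  # the richer model finds h1 = h2 = 0 on GM(1,N)-consistent data
  expect_equal(fit$h1, 0, tolerance = 1e-7)
  expect_equal(fit$h2, 0, tolerance = 1e-7)
  expect_equal(fit$a, 0.25, tolerance = 1e-8)
  expect_equal(predict(fit)$values, pan$reference$values, tolerance = 1e-9)
})

test_that("nsgm validates its contract", {
  facs <- make_factors(2, 9)
  pan <- gen_nsgm_consistent(c(0.3, 0.2), 0.1, 1, 2, facs, 5)
  expect_error(nsgm(pan, train_end = 2003), "at least 5")
  expect_error(predict(nsgm(pan), end_year = 2020), "factor data available")
  dup <- study_panel(pan$reference,
                     c(facs, list(annual_series(3 * facs[[2]]$values, 2000,
                                                name = "F2copy"))))
  expect_error(nsgm(dup), "collinear")
})

test_that("QR solve agrees with lm on the study panel (oracle)", {
  fit <- nsgm(china, train_end = 2016)
  x0 <- china$reference$values[1:17]
  z <- 0.5 * (cumsum(x0)[-1] + cumsum(x0)[-17])
  fago <- apply(factor_matrix(china), 2, cumsum)[2:17, ]
  k1 <- 1:16
  ora <- lm(x0[-1] ~ fago + I(-z) + k1)  # intercept plays the h2 role
  expect_equal(unname(c(fit$h2, fit$b, fit$a, fit$h1)),
               unname(coef(ora)), tolerance = 1e-6)
})
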