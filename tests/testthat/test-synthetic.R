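test_that("consistent generators satisfy their difference equations", {
  # GM(1,1): x(0)(k) + a z(k) - b = 0 at every k
  sim <- gen_gm11_consistent(a = 0.1, b = 5, x1 = 1, m = 8)
  z <- background(ago(sim))
  expect_equal(sim$values[-1] + 0.1 * z - 5, rep(0, 7), tolerance = 1e-12)

  # stationary solution
  expect_equal(gen_gm11_consistent(0, 3, 3, 5)$values, rep(3, 5))
  expect_error(gen_gm11_consistent(-2, 1, 1, 5), "undefined")

  # NSGM: equation residuals zero at every k
  facs <- make_factors(2, 9)
  pan <- gen_nsgm_consistent(b = c(0.3, -0.4), a = 0.2, h1 = 1.5, h2 = -2,
                             factors = facs, x1 = 4)
  zp <- background(ago(pan$reference))
  S <- as.vector(apply(factor_matrix(pan), 2, cumsum) %*% c(0.3, -0.4))
  k <- 2:9
  expect_equal(pan$reference$values[k] + 0.2 * zp,
               S[k] + 1.5 * (k - 1) - 2, tolerance = 1e-12)

  # degeneracy: b = 0, h1 = 0 reduces to GM(1,1) with gray input h2
  pan0 <- gen_nsgm_consistent(b = 0, a = 0.1, h1 = 0, h2 = 5,
                              factors = make_factors(1, 8), x1 = 1)
  expect_equal(pan0$reference$values,
               gen_gm11_consistent(0.1, 5, 1, 8)$values)
})

test_that("parameter recovery across randomized draws (property)", {
  set.seed(2024)
  for (i in 1:100) {
    model <- sample(c("gm11", "gmn", "nsgm"), 1)
    a <- runif(1, -0.6, 0.6)
    if (model == "gm11") {
      b <- runif(1, 0.5, 10)
      fit <- gm11(gen_gm11_consistent(a, b, runif(1, 0.5, 5),
                                      m = sample(5:14, 1)))
      expect_equal(c(fit$a, fit$b), c(a, b), tolerance = 1e-9)
    } else {
      nf <- sample(1:3, 1)
      m <- sample(nf + 5:8, 1)
      b <- runif(nf, -2, 2)
      facs <- random_factors(nf, m)
      if (model == "gmn") {
        fit <- gmn(gen_gmn_consistent(b, a, facs, runif(1, 1, 5)))
        expect_equal(unname(c(fit$a, fit$b)), c(a, b), tolerance = 1e-9)
      } else {
        h <- runif(2, -4, 4)
        fit <- nsgm(gen_nsgm_consistent(b, a, h[1], h[2], facs,
                                        runif(1, 1, 5)))
        expect_equal(unname(c(fit$b, fit$a, fit$h1, fit$h2)),
                     c(b, a, h[1], h[2]), tolerance = 1e-9)
      }
    }
  }
})

test_that("noisy growth panels are reproducible and well-shaped", {
  p1 <- gen_noisy_growth(seed = 99)
  p2 <- gen_noisy_growth(seed = 99)
  expect_identical(p1$reference$values, p2$reference$values)
  expect_identical(factor_matrix(p1), factor_matrix(p2))
  p3 <- gen_noisy_growth(seed = 100)
  expect_false(identical(p1$reference$values, p3$reference$values))

  # strictly positive, so AGO is monotone and normalization valid
  expect_true(all(factor_matrix(p1) > 0) && all(p1$reference$values > 0))

  # noise-free: a factor with dominant weight ranks above the others, and a
  # factor proportional to the reference would score degree 1
  clean <- gen_noisy_growth(m = 12, n_factors = 3,
                            growth_rates = c(0.05, 0.08, 0.11),
                            base = c(100, 100, 100),
                            weights = c(10, 1, 1), noise_sd = 0, seed = 1)
  deg <- gra(clean)$degrees
  expect_identical(names(which.max(deg)), "F1")
  prop <- study_panel(clean$reference, list(
    annual_series(0.5 * clean$reference$values, 2000, name = "P")))
  expect_equal(unname(gra(prop)$degrees), 1)
})

test_that("generated panels flow through the CSV interface", {
  pan <- gen_noisy_growth(m = 6, n_factors = 2, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, tmp)
  back <- load_panel(tmp, reference_name = "REF")
  expect_equal(back$reference$values, pan$reference$values,
               tolerance = 1e-12)
})
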