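test_that("mean normalization rescales to unit mean", {
  expect_equal(mean_normalize(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(mean_normalize(c(1, 2, 3)), c(0.5, 1.0, 1.5))
  n <- mean_normalize(china$reference)
  expect_equal(n[1], 458.66 / mean(china$reference$values))
  expect_equal(mean(n), 1, tolerance = 1e-12)
  expect_error(mean_normalize(c(-1, 1)), "mean is zero")
})

test_that("relational coefficients follow the resolution-coefficient formula", {
  # worked two-series example: ref (1,2,3), factor (3,2,1), xi = 0.5
  ref <- mean_normalize(c(1, 2, 3))
  fac <- list(f = mean_normalize(c(3, 2, 1)))
  res <- relational_coefficients(ref, fac, xi = 0.5)
  expect_equal(res$delta_min, 0)
  expect_equal(res$delta_max, 1)
  expect_equal(as.vector(res$coefficients), c(1/3, 1, 1/3))
  res <- relational_degrees(res)
  expect_equal(unname(res$degrees), 5/9)

  # factor identical to the reference: all coefficients 1 (delta_max = 0)
  res0 <- relational_coefficients(ref, list(f = ref), xi = 0.5)
  expect_equal(as.vector(res0$coefficients), rep(1, 3))

  expect_error(relational_coefficients(ref, list(f = ref[1:2])), "length")
  expect_error(relational_coefficients(ref, fac, xi = 1.5), "\\[0, 1\\]")
})

test_that("degrees, ranks and bounds behave on the study panel", {
  res <- gra(china, xi = 0.5)
  expect_true(all(res$coefficients > 0 & res$coefficients <= 1))
  expect_true(all(res$degrees > 0 & res$degrees <= 1))
  expect_setequal(res$ranks, 1:9)
  # degrees sorted by rank are non-increasing
  expect_true(all(diff(res$degrees[order(res$ranks)]) <= 0))
})

test_that("GRA is invariant to positive rescaling (property)", {
  base <- gra(china)$degrees
  scaled <- china
  scaled$factors <- lapply(china$factors, function(f) {
    f$values <- f$values * runif(1, 0.01, 100); f
  })
  scaled$reference$values <- scaled$reference$values * 1000
  expect_equal(gra(scaled)$degrees, base, tolerance = 1e-12)

  # factors proportional to the reference: all degrees 1
  prop <- study_panel(china$reference, lapply(1:3, function(i) {
    annual_series(i * china$reference$values, 2000, name = paste0("S", i))
  }))
  expect_equal(unname(gra(prop)$degrees), rep(1, 3))
})

test_that("vectorized GRA agrees with a brute-force loop (oracle)", {
  set.seed(11)
  for (rep in 1:10) {
    mat <- matrix(runif(20, 1, 10), nrow = 5, ncol = 4)
    ref <- annual_series(mat[, 1], 2000, name = "R")
    facs <- lapply(2:4, function(j)
      annual_series(mat[, j], 2000, name = paste0("F", j)))
    xi <- runif(1)
    res <- gra(study_panel(ref, facs), xi = xi)

    # direct loop over the defining equations
    nrm <- apply(mat, 2, function(v) v / mean(v))
    delta <- matrix(0, 5, 3)
    for (i in 1:3) for (k in 1:5) delta[k, i] <- abs(nrm[k, 1] - nrm[k, i + 1])
    dmin <- min(delta); dmax <- max(delta)
    beta <- numeric(3)
    for (i in 1:3) {
      eps <- numeric(5)
      for (k in 1:5) eps[k] <- (dmin + xi * dmax) / (delta[k, i] + xi * dmax)
      beta[i] <- mean(eps)
    }
    expect_equal(unname(res$degrees), beta, tolerance = 1e-12)
  }
})
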