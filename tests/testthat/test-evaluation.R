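test_that("residual percentage follows its definition", {
  expect_equal(residual_percent(5, 5), 0)
  expect_equal(round2(residual_percent(5259.83, 5188.14), 2), 1.36)
  expect_equal(round2(residual_percent(5912.19, 6587.9), 2), 11.43)
  expect_equal(residual_percent(c(2, 4), c(1, 5)), c(50, 25))
  expect_error(residual_percent(0, 1), "undefined")
})

test_that("evaluate splits train/test and averages residuals", {
  act <- annual_series(c(10, 20, 30, 40, 50, 60), 2000, name = "Y")
  pred <- annual_series(c(10, 22, 27, 40, 55, 54), 2000, name = "Yhat")
  rep <- evaluate(pred, act, train_years = c(2000, 2003),
                  test_years = c(2004, 2005))
  expect_true(is.na(rep$rows$phi[1]))              # anchored first year
  expect_equal(rep$rows$phi[2:4], c(10, 10, 0))
  expect_equal(rep$re_train, mean(c(10, 10, 0)))   # first year excluded
  expect_equal(rep$re_test, mean(c(10, 10)))       # unweighted mean

  perfect <- evaluate(act, act, c(2000, 2003), c(2004, 2005))
  expect_equal(perfect$re_train, 0)
  expect_equal(perfect$re_test, 0)

  expect_error(evaluate(pred, act, c(2000, 2004), c(2004, 2005)),
               "after the training window")
  short <- annual_series(c(10, 20), 2000, name = "Yhat")
  expect_error(evaluate(short, act, c(2000, 2003), c(2004, 2005)),
               "does not cover")
})

test_that("test-average equals the mean of the printed test residuals", {
  # published GM(1,1) and NSGM test rows
  expect_equal(round2(mean(c(8.07, 11.43)), 2), 9.75)
  expect_equal(round2(mean(c(1.36, 2.34)), 2), 1.85)
  # and the published GM(1,10) test rows average to 6.905 (rounding 6.91),
  # not the printed 6.82 — the computed mean is what evaluate() reports
  expect_equal(mean(c(7.43, 6.38)), 6.905)
})

test_that("growth statistics reproduce endpoint arithmetic", {
  g <- growth_stats(china$reference)
  expect_equal(round2(g$total_growth_pct, 2), 1189.01)
  expect_equal(round2(g$cagr_pct, 2), 15.26)
  # constant series: zero growth
  g0 <- growth_stats(annual_series(rep(7, 5), 2000))
  expect_equal(g0$total_growth_pct, 0)
  expect_equal(g0$cagr_pct, 0)
  expect_error(growth_stats(annual_series(c(0, 1, 2, 3), 2000)), "zero start")
})

test_that("elasticity and shares behave", {
  expect_equal(round2(elasticity(china, "THE", "GDP", 2009, 2018), 2), 1.30)
  # a series against itself has elasticity 1
  expect_equal(elasticity(china, "GDP", "GDP"), 1)
  expect_equal(round2(expenditure_share(china, "OOP", "THE", 2000), 2),
               58.98)
  expect_error(expenditure_share(china, "XXX", "THE", 2000), "no series")
  expect_error(elasticity(china, "THE", "GDP", 2009, 2030), "outside")
})

test_that("descriptive_stats assembles the financing summary", {
  st <- descriptive_stats(china)
  expect_identical(nrow(st$growth), 10L)
  expect_setequal(unique(st$shares$numerator), c("OOP", "GGHE", "THE"))
  the_gdp <- st$shares[st$shares$numerator == "THE", ]
  expect_equal(round2(the_gdp$percent[the_gdp$year == 2000], 2), 4.57)
  expect_equal(round2(the_gdp$percent[the_gdp$year == 2018], 2), 6.57)
  expect_equal(round2(st$elasticity, 2), 1.18)
})
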