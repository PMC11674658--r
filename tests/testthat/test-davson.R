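test_that("Davson's equation recovers the published reference states", {
  expect_equal(davson_icp(0.48, 12.36, 4.91), 10.8428)   # median NPH cohort
  expect_equal(davson_icp(0.40, 10, 7.5), 11.5)          # the normal state
  expect_equal(davson_icp(5, 0, 7.5), 7.5)               # zero resistance limit
  expect_equal(davson_rout(13, 0.25, 7.5), 22)
  expect_equal(davson_rout(13, 1.32, 7.5), 5.5 / 1.32)   # ~4.2
  expect_equal(davson_rout(11.5, 0.40, 7.5), 10)
  expect_error(davson_rout(13, 0, 7.5), "csf_formation")
})

test_that("Davson ICP and R_out are exact inverses for random positive triples", {
  set.seed(202)
  f <- stats::runif(200, 0.05, 2)
  r <- stats::runif(200, 0.5, 40)
  p <- stats::runif(200, 0, 15)
  expect_equal(davson_rout(davson_icp(f, r, p), f, p), r, tolerance = 1e-12)
})

test_that("the age regression for normal outflow resistance is linear", {
  expect_equal(rout_age_regression(0), 9.88)
  expect_equal(rout_age_regression(60), 14.38)
  expect_equal(rout_age_regression(41.6), 13.0)
  expect_error(rout_age_regression(-5), "age")
})

test_that("the formation-rate correction reduces the apparent outflow resistance", {
  expect_equal(corrected_rout(17.3, 1.0, 0.21), 17.3 / 1.21)  # ~14.3
  expect_equal(corrected_rout(17.3, 1.0, 0), 17.3)            # zero-correction limit
  expect_equal(corrected_rout(8, 1, 0), 8)
  expect_error(corrected_rout(17.3, 0.5, -0.5), "> 0")
  # strictly decreasing in the formation-rate increase
  inc <- seq(0, 1, by = 0.05)
  expect_true(all(diff(corrected_rout(17.3, 1.0, inc)) < 0))
})

test_that("overestimation percent reproduces the 23% and 33% headline figures", {
  expect_equal(overestimation_percent(17.6, corrected_rout(17.3, 1.0, 0.21)),
               23, tolerance = 0.01)
  expect_equal(overestimation_percent(13, 9.8), 100 * 3.2 / 9.8)  # ~32.7 -> 33
  expect_equal(overestimation_percent(5, 5), 0)
  # strictly increasing in the apparent value at fixed corrected value
  app <- seq(10, 30, by = 1)
  expect_true(all(diff(overestimation_percent(app, 9.8)) > 0))
  expect_error(overestimation_percent(13, 0), "> 0")
})

test_that("the correction report assembles the headline numbers", {
  rep <- correction_report()
  expect_equal(rep$corrected_rout, 17.3 / 1.21)
  expect_equal(round(rep$corrected_rout, 1), 14.3)
  expect_equal(round(rep$overestimation_pct), 23)
  expect_equal(rep$back_calculated_rate, 17.3 / 17.6)  # ~0.983 mL/min
  expect_equal(rep$csf_fr_increase, 0.21)
})

test_that("the regional partition recovers the grey-matter flow reduction", {
  expect_equal(regional_grey_reduction(0.65, 0.35, 1.7, 0.20, 0.40),
               0.137, tolerance = 0.005)
  # uniform case: white reduction equal to global implies grey equals global
  expect_equal(regional_grey_reduction(0.65, 0.35, 1.7, 0.2, 0.2), 0.2)
  # symmetric algebra: equal masses, unit perfusion ratio
  expect_equal(regional_grey_reduction(0.5, 0.5, 1.0, 0.2, 0.4), 0.0)
  expect_error(regional_grey_reduction(0.6, 0.3, 1.7, 0.2, 0.4), "sum to 1")
  # recomposition: the flow-share weights recover the global reduction exactly
  w_g <- 0.65 * 1.7 / (0.65 * 1.7 + 0.35)
  g <- regional_grey_reduction(0.65, 0.35, 1.7, 0.20, 0.40)
  expect_equal(w_g * g + (1 - w_g) * 0.40, 0.20, tolerance = 1e-15)
})

test_that("Starling flux: sign convention, linearity and monotonicity", {
  expect_equal(starling_flux(1, 12, 1, 25), -13)   # intact barrier absorbs
  expect_equal(starling_flux(0, 12, 1, 25), 0)
  expect_equal(starling_flux(2, 12, 0, 25), 2 * 12)  # fully leaky barrier
  expect_equal(starling_flux(3, 12, 1, 25), 3 * starling_flux(1, 12, 1, 25))
  tmps <- seq(0, 40, by = 1)
  expect_true(all(diff(starling_flux(1.5, tmps, 0.9, 25)) > 0))
  expect_error(starling_flux(1, 12, 1.2, 25), "reflection_coefficient")
})
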