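test_that("capillary volume is clamped, continuous, non-decreasing and bounded", {
  expect_equal(capillary_volume_from_tmp(12), 20.3)
  expect_equal(capillary_volume_from_tmp(5), 20.3)     # below-floor clamp
  expect_equal(capillary_volume_from_tmp(37.9), 29.2)  # elastic limit
  expect_equal(capillary_volume_from_tmp(100), 29.2)
  expect_equal(capillary_volume_from_tmp(24.95), 20.3 * (1 + 0.017 * 12.95))
  tmp <- seq(-10, 60, by = 0.01)
  v <- capillary_volume_from_tmp(tmp)
  expect_true(all(v >= 20.3 & v <= 29.2))
  expect_true(all(diff(v) >= 0))
  expect_lt(max(abs(diff(v))), 0.005)  # no jumps at the clamp corners
})

test_that("an internally inconsistent capillary law is rejected", {
  expect_error(capillary_law(slope = 0.02), "inconsistent")
})

test_that("the venous quadratic evaluates and saturates as calibrated", {
  expect_equal(venous_tmp_change_from_volume(0), -3.44)
  expect_equal(venous_tmp_change_from_volume(32),
               -0.033 * 32^2 + 7.49 * 32 - 3.44)  # ~202.4
  law <- venous_law()
  expect_equal(law$dv_vertex, 7.49 / (2 * 0.033))          # ~113.5 %
  expect_equal(law$dtmp_max, 7.49^2 / (4 * 0.033) - 3.44)  # ~421.6 %
  expect_equal(venous_tmp_change_from_volume(law$dv_vertex), law$dtmp_max)
  expect_error(venous_tmp_change_from_volume(150), "elastic limit")
})

test_that("the venous inversion takes the proximal branch, both signs", {
  expect_equal(venous_volume_change_from_tmp(96), 14.15966, tolerance = 1e-5)
  expect_equal(venous_volume_change_from_tmp(200), 31.54606, tolerance = 1e-5)
  expect_equal(venous_volume_change_from_tmp(-96),
               (7.49 - sqrt(7.49^2 + 4 * 0.033 * 92.56)) / 0.066,  # ~-11.75
               tolerance = 1e-9)
  # saturation raises, never clamps silently
  err <- tryCatch(venous_volume_change_from_tmp(500), error = identity)
  expect_s3_class(err, "cvchain_saturation_error")
  expect_match(conditionMessage(err), "elastic limit")
})

test_that("forward and inverse venous laws round-trip on the proximal branch", {
  dv <- seq(-40, 100, by = 2.5)
  back <- venous_volume_change_from_tmp(venous_tmp_change_from_volume(dv))
  expect_equal(back, dv, tolerance = 1e-9)
})

test_that("the venous inversion matches a brute-force scan of the quadratic", {
  # independent oracle: scan volume changes at 1e-4 resolution and pick the
  # argmin of |quadratic - target|
  grid <- seq(-50, 113.5, by = 1e-4)
  qv <- -0.033 * grid^2 + 7.49 * grid - 3.44
  set.seed(303)
  targets <- stats::runif(100, min = -0.033 * 2500 - 7.49 * 50 - 3.44, max = 420)
  oracle <- vapply(targets, function(t) grid[which.min(abs(qv - t))], numeric(1))
  expect_equal(venous_volume_change_from_tmp(targets), oracle, tolerance = 1e-3)
})

test_that("cuff resistance law: literal evaluation, clamping, policy mode", {
  lit <- cuff_law(mode = "literal")
  expect_equal(cuff_resistance(0, lit), 0.008)
  expect_equal(cuff_resistance(7.5, lit), 0)  # maximal dilation at drainage
  expect_equal(cuff_resistance(-4, lit), 2.71 * 4 + 0.008)
  expect_equal(cuff_resistance(-5.5, cuff_law(mode = "scaled", scale_factor = 2)),
               2 * (2.71 * 5.5 + 0.008))
  # policy-driven returns the scenario-prescribed value (x2 of normal here)
  expect_equal(cuff_resistance(-5.5, cuff_law(), reference_resistance = 2 * 6.5 / 750),
               13 / 750)
  expect_error(cuff_resistance(-5.5, cuff_law()), "prescribed")
  # never negative in any mode
  tmps <- seq(-30, 30, by = 0.5)
  for (law in list(lit, cuff_law(mode = "scaled", scale_factor = 0.001)))
    expect_true(all(cuff_resistance(tmps, law) >= 0))
})
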