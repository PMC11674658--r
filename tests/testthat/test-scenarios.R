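test_that("the catalogue holds the study scenarios with their prescriptions", {
  cat <- scenario_catalogue()
  expect_true(all(c("normal", "nph_baseline", "cbf_restore", "cbf_minus40",
                    "cbf_minus57", "infusion", "drainage", "mid_icp",
                    "cortex", "white_matter") %in% names(cat)))
  # infusion: ICP 13+17, arterial pressure 100+8, flow 525
  expect_equal(cat$infusion$icp, 30)
  expect_equal(cat$infusion$arterial_pressure, 108)
  expect_equal(cat$infusion$prescribed_flow, 525)
  expect_equal(cat$infusion$arterial_multiplier, 0.961)
  # NPH baseline: doubled cuff, +25% artery
  expect_equal(cat$nph_baseline$arterial_multiplier, 1.25)
  expect_equal(cat$nph_baseline$cuff_multiplier, 2)
  # regional variants and the profound-ischemia flow
  expect_equal(cat$cbf_minus57$prescribed_flow, 322.5)
  expect_equal(cat$cortex$prescribed_flow, 750 * (1 - 0.137))
  expect_equal(cat$white_matter$prescribed_flow, 450)
  expect_equal(cat$drainage$icp, 0)
  expect_identical(cat$drainage$cuff_policy, "zero")
})

test_that("every catalogue scenario passes closure validation", {
  for (sc in scenario_catalogue())
    expect_invisible(validate_scenario(sc))
})

test_that("over- and under-determined scenarios are rejected before solving", {
  expect_error(
    chain_scenario("bad", icp = 10, prescribed_flow = NA_real_,
                   arterial_policy = "solve-residually",
                   cuff_policy = "zero"),
    "under-determined")
  expect_error(
    chain_scenario("bad2", icp = 10, prescribed_flow = 600,
                   arterial_policy = "multiplier-of-normal",
                   cuff_policy = "zero"),
    "arterial_multiplier")
  expect_error(chain_scenario("bad3", icp = -2, prescribed_flow = 600,
                              arterial_policy = "multiplier-of-normal",
                              arterial_multiplier = 1, cuff_policy = "zero"),
               "icp")
})

test_that("scenarios round-trip through YAML serialization", {
  cat <- scenario_catalogue()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios(cat, path)
  back <- read_scenarios(path)
  expect_identical(names(back), names(cat))
  for (nm in names(cat))
    expect_equal(back[[nm]], cat[[nm]])
  # units block is declared in the document header
  doc <- yaml::read_yaml(path)
  expect_identical(doc$units$pressure, "mmHg")
  expect_identical(doc$units$flow, "mL/min")
})

test_that("the 'normal' scenario solved as-is returns the baseline unchanged", {
  st <- solve_chain("normal")
  pc <- normal_baseline()
  expect_equal(st$flow, pc$cbf)
  expect_equal(st$segments$inlet_pressure[1], 100)
  expect_equal(st$segments$inlet_pressure[2], 32)   # 100 - 750 x R_art
  expect_equal(st$segments$inlet_pressure[4], 14)   # 7.5 + 750 x R_cuf
  expect_equal(st$segments$outlet_pressure[4], pc$sinus_pressure)
  expect_equal(st$venous_tmp, 2.5)        # 14 - 11.5
  expect_equal(st$cuff_tmp, -4)           # 7.5 - 11.5
  # the venous quadratic does not pass exactly through the origin (constant
  # term -3.44%), so the post-capillary pressure and the mean capillary TMP
  # are recovered to ~0.01 mmHg, not to machine precision
  expect_equal(st$segments$inlet_pressure[3], 15, tolerance = 1e-3)
  expect_equal(st$capillary_tmp, 12, tolerance = 1e-3)
  expect_lt(abs(st$report$venous_volume_change_pct), 0.5)
})
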