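test_that("the NPH baseline reproduces a near-normal capillary TMP", {
  st <- .states("nph_baseline")
  expect_equal(st$capillary_tmp, 12.2, tolerance = 0.01)  # 12.257 mmHg
  expect_equal(st$venous_tmp, 4.9)        # 17.9 - 13, pinned by the boundary
  expect_equal(st$report$venous_volume_change_pct, 14.15966, tolerance = 1e-4)
  expect_identical(st$report$closure, "capillary-residual")
})

test_that("re-evaluating the response laws at a converged state is a fixed point", {
  laws <- chain_laws()
  rn <- normal_resistances(normal_baseline())
  for (nm in c("cbf_restore", "cbf_minus57", "infusion", "drainage", "mid_icp")) {
    st <- .states(nm)
    seg <- st$segments
    tol <- 1e-9 * max(1, abs(st$capillary_tmp))
    # capillary law at the state's own TMP returns the state's resistance/volume
    expect_equal(capillary_volume_from_tmp(st$capillary_tmp), seg$volume[2],
                 tolerance = 1e-9)
    expect_equal(rn[["capillary"]] *
                   resistance_scale_from_volume(seg$volume[2] / 20.3),
                 seg$resistance[2], tolerance = 1e-9)
    # venous law at the state's own venous TMP returns the state's dilation
    dtmp <- 100 * (st$venous_tmp - 2.5) / 2.5
    expect_equal(venous_volume_change_from_tmp(dtmp),
                 st$report$venous_volume_change_pct, tolerance = 1e-9)
    # and the mean capillary TMP is self-consistent with the pressures
    expect_lt(abs(mean_transmural_pressure(seg$inlet_pressure[2],
                                           seg$outlet_pressure[2], st$icp) -
                    st$capillary_tmp), tol)
  }
})

test_that("drainage solves the flow and matches a brute-force flow scan", {
  st <- .states("drainage")
  expect_equal(100 * (st$flow - 600) / 600, 14.5, tolerance = 0.1)
  expect_identical(st$report$closure, "flow-residual")

  # independent oracle: scan flow at 0.01 mL/min resolution; for each
  # candidate, pressures follow from the two boundaries and the residual is
  # the capillary-law mismatch of the pressure balance
  r_art <- 1.25 * 68 / 750
  dv <- (7.49 - sqrt(7.49^2 - 4 * 0.033 * (3.44 + 200))) / (2 * 0.033)
  r_ven <- (1 / 750) * (1 + dv / 100)^-2
  q <- seq(1, 1500, by = 0.01)
  p1 <- 100 - q * r_art
  p2 <- 7.5 + q * r_ven
  tmp <- (p1 + p2) / 2            # ICP = 0
  vcap <- pmin(29.2, 20.3 * (1 + 0.017 * pmax(0, tmp - 12)))
  r_cap <- (17 / 750) * (vcap / 20.3)^-2
  resid <- abs(p1 - p2 - q * r_cap)
  expect_lt(abs(q[which.min(resid)] - st$flow), 0.02)
})

test_that("a zero prescribed flow is the degenerate no-loss endpoint", {
  sc <- chain_scenario("stasis", icp = 11.5, prescribed_flow = 0,
                       arterial_policy = "multiplier-of-normal",
                       arterial_multiplier = 1,
                       cuff_policy = "multiplier-of-normal",
                       cuff_multiplier = 1, reference_state = "stasis")
  st <- solve_chain(sc)
  drops <- st$segments$inlet_pressure - st$segments$outlet_pressure
  # no viscous loss across any law-governed segment
  expect_equal(drops[c(1, 3, 4)], c(0, 0, 0))
  # internal pressures equal their adjacent boundary values
  expect_equal(st$segments$inlet_pressure[2], 100)
  expect_equal(st$segments$outlet_pressure[2], 7.5)
  expect_true("degenerate zero-flow endpoint" %in% st$report$notes)
})

test_that("capillary TMP increases strictly with prescribed flow at fixed ICP and cuff", {
  flows <- c(350, 450, 550, 650, 750)
  tmps <- vapply(flows, function(q) {
    sc <- chain_scenario(paste0("q", q), icp = 13, prescribed_flow = q,
                         arterial_policy = "solve-residually",
                         cuff_policy = "unchanged-from-reference",
                         reference_state = "nph_baseline")
    solve_chain(sc)$capillary_tmp
  }, numeric(1))
  expect_true(all(diff(tmps) > 0))
})

test_that("capillary TMP is near-linear in CBF across the four flow scenarios", {
  fam <- sweep_scenarios(c("cbf_minus57", "cbf_minus40", "nph_baseline",
                           "cbf_restore"))
  expect_true(all(fam$converged))
  expect_gte(stats::cor(fam$cbf_mL_min, fam$capillary_tmp_mmHg), 0.99)
  expect_equal(round(fam$capillary_tmp_mmHg, 1), c(4.3, 8.0, 12.3, 15.6))
})

test_that("the solver is deterministic: identical inputs, identical states", {
  a <- solve_chain("infusion")
  b <- solve_chain("infusion")
  expect_identical(a, b)
})

test_that("the infusion state reports its vein dilation against the quoted 32%", {
  st <- .states("infusion")
  expect_gt(st$report$venous_volume_change_pct, 32)  # solved ~52%
  expect_true(any(grepl("vein dilation", st$report$notes)))
  expect_identical(st$report$closure, "cuff-residual")
  # the cuff TMP magnitude quadruples relative to the NPH baseline (-5.5 -> -22.5)
  expect_equal(st$cuff_tmp / .states("nph_baseline")$cuff_tmp, 22.5 / 5.5)
})

test_that("sweeps keep failed rows as flagged gaps and empty families stay empty", {
  expect_identical(nrow(sweep_scenarios(list())), 0L)
  bad <- chain_scenario("impossible", icp = 200, prescribed_flow = 600,
                        arterial_policy = "multiplier-of-normal",
                        arterial_multiplier = 1.25,
                        cuff_policy = "multiplier-of-normal",
                        cuff_multiplier = 2, reference_state = "impossible")
  tab <- sweep_scenarios(list(bad, scenario_catalogue()$nph_baseline))
  expect_identical(tab$converged, c(FALSE, TRUE))
  expect_true(is.na(tab$capillary_tmp_mmHg[1]))
  expect_false(is.na(tab$capillary_tmp_mmHg[2]))
})

test_that("figure data for the ICP family carries the post-shunt anchor row", {
  tab <- figure_data("icp_tmp")
  expect_identical(tab$scenario,
                   c("drainage", "nph_baseline", "mid_icp", "infusion",
                     "post_shunt_reference"))
  anchor <- tab[tab$scenario == "post_shunt_reference", ]
  expect_equal(anchor$venous_volume_change_pct, -12.8)
  expect_true(is.na(anchor$capillary_tmp_mmHg))  # a constant, not a solved state
})
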