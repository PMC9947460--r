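# Boundary-load laws and unit conversions.

test_that("pressure conversions reproduce the quoted clinical pairs", {
  expect_equal(pressure_convert(10, "mmHg", "cmH2O"), 13.6)
  expect_equal(pressure_convert(20, "cmH2O", "Pa"), 1961.33)
  expect_equal(pressure_convert(0, "mmHg", "Pa"), 0)
  # round trip
  expect_equal(pressure_convert(pressure_convert(7.3, "Pa", "mmHg"),
                                "mmHg", "Pa"), 7.3)
  expect_error(pressure_convert(1, "mmHg", "psi"))
})

test_that("muscle tension law: hand value, monotonicity, linearity in M", {
  expect_equal(eom_force(0, 1), 4 * (4.79 - 3.01), tolerance = 1e-12)
  expect_equal(eom_force(0, 1), 7.12, tolerance = 1e-12)
  w <- seq(0, 10, by = 0.1)
  expect_true(all(diff(eom_force(w, 1)) > 0))
  expect_equal(eom_force(w, 2), 2 * eom_force(w, 1))
  expect_equal(eom_force(3.3, 0), 0)
  # inversion by root finding: the displacement at 25.3 mN
  w253 <- eom_w_from_force(25.3, M = 1)
  expect_equal(w253, 3.52, tolerance = 0.01)
  expect_equal(eom_force(w253, 1), 25.3, tolerance = 1e-8)
})

test_that("optic-nerve slack arithmetic and spring threshold", {
  expect_equal(on_slack(50, 40, 24), -2)
  expect_equal(on_slack(58.8, 40.26, 24.72), 6.18)
  # no tension below the slack, continuous at it, linear beyond
  expect_equal(on_spring_force(4.66, slack = 6, k = 1), 0)
  expect_equal(on_spring_force(6, slack = 6, k = 1), 0)
  expect_equal(on_spring_force(7, slack = 6, k = 1), 1)
  expect_equal(on_spring_force(8, slack = 6, k = 2.5), 5)
})

test_that("load case validates its physical ranges", {
  expect_error(load_case(ICP = 50), "ICP")
  expect_error(load_case(M = 3), "M")
  expect_error(load_case(eps_H_fat = c(0.02, 0.01)), "non-decreasing")
  lc <- load_case()
  expect_equal(lc$eps_H_fat[1], 0)
  expect_equal(max(lc$eps_H_fat), 0.070)
  expect_equal(length(lc$eps_H_fat), 14)
})

test_that("ICP band traction: zero, linear in ICP, closed-form resultants", {
  geom <- build_anatomy(anatomy_params())
  expect_equal(icp_traction(0, geom)$axial_resultant_mN, 0)
  t1 <- icp_traction(10, geom)
  t2 <- icp_traction(20, geom)
  expect_equal(t2$axial_resultant_mN, 2 * t1$axial_resultant_mN)
  # sub-arachnoid roof (default): annulus from the canal edge to R_Di;
  # ~1 mN at the terrestrial 13.6 cmH2O
  expect_equal(icp_traction(13.6, geom)$band[["outer"]], 1.0)
  expect_gt(icp_traction(13.6, geom)$axial_resultant_mN, 0.7)
  expect_lt(icp_traction(13.6, geom)$axial_resultant_mN, 1.3)
  # alternative outer annulus: p * pi * ((R_Do + b)^2 - R_Do^2)
  p <- anatomy_params()
  a_mm2 <- pi * ((p$R_Do + 0.27)^2 - p$R_Do^2)
  expect_equal(icp_traction(13.6, geom, "outer_annulus")$axial_resultant_mN,
               1333.7044 * a_mm2 * 1e-3, tolerance = 1e-6)
})
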