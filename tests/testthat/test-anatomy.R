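# Parametric anatomy, presets, geometry construction.

test_that("baseline parameters carry the reference values", {
  p <- anatomy_params()
  expect_equal(p$R_Eq, 12.36)
  expect_equal(p$R_P, 12.36)
  expect_equal(p$h_Eq, 0.5)
  expect_equal(p$h_P, 1.0)
  expect_equal(p$R_OM, 13.95)
  expect_equal(p$L_OM, 9.51)
  expect_equal(p$L_O, 40.26)
  expect_equal(p$R_A, 0.85)
  expect_equal(p$R_Di, 1.0)
  expect_equal(p$R_Do, 1.515)
  expect_equal(p$sas_band, 270)
})

test_that("invariant violations name the violated constraint", {
  expect_error(anatomy_params(R_Di = 0.5), "R_Di > R_A")
  expect_error(anatomy_params(R_Do = 0.9), "R_Do > R_Di")
  expect_error(anatomy_params(R_OM = 10), "R_OM > R_Eq")
  expect_error(anatomy_params(L_O = 24), "L_O > 2")
  expect_error(anatomy_params(h_Eq = -1), "positive")
})

test_that("presets apply exactly one named perturbation", {
  base <- preset_case("baseline")
  expect_equal(base$loads$ICP, 13.6)
  expect_equal(base$loads$M, 1)
  expect_equal(base$tissues$E[base$tissues$name == "ocular_coats"], 1.5e6)

  lo <- preset_case("plus10_LO")
  expect_equal(lo$params$L_O, 44.286)
  expect_equal(lo$params$R_Eq, base$params$R_Eq)

  expect_equal(preset_case("plus10_RP")$params$R_P, 12.36 * 1.1)
  expect_equal(preset_case("plus10_REq")$params$R_Eq, 12.36 * 1.1)
  expect_equal(preset_case("plus10_ROM")$params$R_OM, 13.95 * 1.1)
  expect_equal(preset_case("plus10_LOM")$params$L_OM, 9.51 * 1.1)

  soft <- preset_case("soft_sclera_0.25")
  expect_equal(soft$tissues$E[soft$tissues$name == "ocular_coats"], 0.25e6)
  expect_equal(preset_case("icp_20")$loads$ICP, 20)
  expect_equal(preset_case("active_eom")$loads$M, 2.25)

  # determinism: the same preset twice is identical
  expect_identical(preset_case("baseline"), preset_case("baseline"))
  expect_error(preset_case("nonsense"), "unknown preset")
})

test_that("geometry construction is deterministic and hash-stable", {
  g1 <- build_anatomy(anatomy_params())
  g2 <- build_anatomy(anatomy_params())
  expect_identical(geometry_hash(g1), geometry_hash(g2))
  g3 <- build_anatomy(preset_case("plus10_LO")$params)
  expect_false(identical(geometry_hash(g1), geometry_hash(g3)))
})

test_that("spherical parameters give a spherical shell of uniform thickness", {
  g <- build_anatomy(anatomy_params(R_Eq = 12, R_P = 12, h_Eq = 0.7, h_P = 0.7))
  th <- seq(0, pi, length.out = 50)
  rin <- g$curves$inner_ell(th)
  rout <- g$curves$outer_ell(th)
  din <- sqrt(rin[, 1]^2 + (rin[, 2] - g$zc)^2)
  dout <- sqrt(rout[, 1]^2 + (rout[, 2] - g$zc)^2)
  expect_equal(din, rep(12, 50), tolerance = 1e-12)
  expect_equal(dout - din, rep(0.7, 50), tolerance = 1e-12)
})

test_that("shell thickness blends smoothly and monotonically pole to equator", {
  g <- build_anatomy(anatomy_params())
  th <- seq(pi / 2, pi, length.out = 200) # equator to posterior pole
  rin <- g$curves$inner_ell(th)
  rout <- g$curves$outer_ell(th)
  h <- sqrt((rout[, 1] - rin[, 1])^2 + (rout[, 2] - rin[, 2])^2)
  expect_equal(h[1], 0.5, tolerance = 1e-9)
  expect_equal(h[length(h)], 1.0, tolerance = 1e-9)
  expect_true(all(diff(h) > -1e-9))
})

test_that("region polygons are positive and the globe clears the wall", {
  g <- build_anatomy(anatomy_params())
  expect_true(all(g$areas > 0))
  # every point of the globe inside the orbit must clear the wall
  z <- seq(g$zc - g$b_o + 0.1, g$params$L_O, length.out = 200)
  rg <- g$a_o * sqrt(pmax(1 - ((z - g$zc) / g$b_o)^2, 0))
  expect_true(all(g$wall_r(z) - rg > 0.2))
})
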