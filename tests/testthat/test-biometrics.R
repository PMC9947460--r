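# Biometric post-processing on real solution states.

test_that("undeformed measures match the reference geometry", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_eye(geom, "coarse", 2)
  u0 <- numeric(2 * nrow(mesh$nodes))
  # posterior ROC of the undeformed outer surface: the osculating radius of
  # the outer ellipse at its pole, a^2/b
  roc <- posterior_roc(mesh, u0)
  expect_equal(roc, 12.86^2 / 13.36, tolerance = 0.01)
  # peripapillary arc equals the analytic inner-ellipse arc of the labelled
  # segment (posterior quarter, ending at the scleral canal)
  th <- seq(3 * pi / 4, geom$theta_cut, length.out = 4000)
  P <- geom$curves$inner_ell(th)
  arc_exact <- sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
  expect_equal(peripapillary_arc(mesh, u0, 1 / 4), arc_exact, tolerance = 1e-4)
  # smaller fractions give nested, shorter segments
  a8 <- peripapillary_arc(mesh, u0, 1 / 8)
  a4 <- peripapillary_arc(mesh, u0, 1 / 4)
  a2 <- peripapillary_arc(mesh, u0, 1 / 2)
  expect_true(a8 < a4 && a4 < a2)
})

test_that("rigid axial translation changes neither ROC nor arc length", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_eye(geom, "coarse", 2)
  u0 <- numeric(2 * nrow(mesh$nodes))
  ut <- u0
  ut[seq(2, length(ut), 2)] <- 2.5 # uniform anterior translation
  expect_equal(posterior_roc(mesh, ut), posterior_roc(mesh, u0),
               tolerance = 1e-9)
  expect_equal(peripapillary_arc(mesh, ut), peripapillary_arc(mesh, u0),
               tolerance = 1e-9)
  ax <- axial_measures(mesh, ut, u0)
  expect_equal(ax$proptosis_mm, 2.5)
  expect_equal(ax$dAL_um, 0, tolerance = 1e-9)
})

test_that("arc shortening holds for the quarter and half definitions", {
  pr <- baseline_run()
  uC <- pr$C$u
  arcs <- sapply(c(1 / 4, 1 / 2), function(f) {
    sapply(pr$D[c(5, 10, 14)], function(st)
      peripapillary_arc(pr$mesh, st$u, f) - peripapillary_arc(pr$mesh, uC, f))
  })
  # shortening, growing monotonically along the swelling ramp
  expect_true(all(arcs < 0))
  expect_true(all(apply(arcs, 2, diff) < 0))
  # the innermost eighth (stiff flange next to the canal) moves least
  a8 <- peripapillary_arc(pr$mesh, pr$D[[14]]$u, 1 / 8) -
    peripapillary_arc(pr$mesh, uC, 1 / 8)
  expect_lt(abs(a8), abs(arcs[3, 1]))
})

test_that("force balance report matches its components", {
  pr <- baseline_run()
  fb <- force_balance(pr$D[[14]])
  expect_equal(fb$residual, fb$F_ICP + fb$F_fat - fb$F_EOM - fb$F_ON)
  expect_lt(abs(fb$residual), 1e-3 * fb$F_EOM)
})
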