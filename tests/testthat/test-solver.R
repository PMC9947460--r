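# Equilibrium solver: analytic oracles and structural checks.

test_that("an unloaded body stays undeformed", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_eye(geom, "coarse", 2)
  st <- solve_equilibrium(mesh, tissue_registry(), load_case(),
                          pars = list(eps_v = 0, ICP = 0))
  expect_equal(max(abs(st$u)), 0, tolerance = 1e-12)
  expect_true(st$converged)
})

test_that("thin-shell inflation matches the incompressible closed form", {
  # sphere R = 12 mm, h = 0.5 mm, E = 1.5 MPa, internal pressure 15 mmHg:
  # u = p R^2 (1 - nu) / (2 E h) at the mid-surface with nu = 1/2
  params <- anatomy_params(R_Eq = 12, R_P = 12, h_Eq = 0.5, h_P = 0.5)
  geom <- build_anatomy(params)
  mesh <- mesh_eye(geom, "coarse", 2)
  ns <- asNamespace("orbitfem")
  ctx <- ns$solve_context(mesh, tissue_registry(), load_case(iop_mode = "direct"),
                          stage = "eye", direct_iop = TRUE, pin = "anterior_pole")
  st <- ns$newton_solve(ctx, numeric(ctx$ndof),
                        list(eps_v = 0, eps_fat = 0, ICP = 0, M = 0, IOP = 15))
  expect_true(st$converged)
  ids <- mesh$chains$outer_sclera
  th <- mesh$sets$outer_theta
  un <- st$u[2 * ids - 1] * sin(th) + st$u[2 * ids] * cos(th)
  sel <- th > pi / 3 & th < 2 * pi / 3 # far from the nerve-head perturbation
  p <- pressure_convert(15, "mmHg", "Pa")
  closed <- p * 12.25^2 * 0.5 / (2 * 1.5e6 * 0.5)
  expect_equal(mean(un[sel]), closed, tolerance = 0.03)
})

test_that("unconfined swelling is stress-free isotropic expansion", {
  # with no kinematic confinement the exact solution is the uniform expansion
  # u = (J_H^(1/3) - 1) X: elastic volume ratio 1, zero hydrostatic stress
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_fat(geom, "coarse", 2)
  ns <- asNamespace("orbitfem")
  ctx <- ns$solve_context(mesh, tissue_registry(), load_case(), stage = "eye")
  ctx$fixed <- c(2L * mesh$sets$axis - 1L, 2L * mesh$chains$fat_inner[1])
  eps <- 0.03
  st <- ns$newton_solve(ctx, numeric(ctx$ndof),
                        list(eps_v = 0, eps_fat = eps, ICP = 0, M = 0, IOP = 0))
  expect_true(st$converged)
  ef <- element_fields(mesh, tissue_registry(), st$u, eps_fat = eps)
  expect_lt(max(abs(ef[, "Je"] - 1)), 1e-6)
  mu_fat <- tissue_registry()$mu[3]
  expect_lt(max(abs(ef[, "hydro"])), mu_fat)
  # radial displacement is the isotropic stretch of the radius
  lam <- (1 + eps) - 1
  ur <- st$u[2 * mesh$chains$fat_inner - 1]
  expect_equal(ur, lam * mesh$nodes[mesh$chains$fat_inner, 1],
               tolerance = 1e-5)
})

test_that("fully confined swelling develops the volumetric pressure", {
  # clamping every fat boundary forces J = 1, so J/J_H = 1/J_H and the
  # pressure is kappa (1 - J_H)/J_H, uniform
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_fat(geom, "coarse", 2)
  ns <- asNamespace("orbitfem")
  ctx <- ns$solve_context(mesh, tissue_registry(), load_case(), stage = "eye")
  bd <- unique(c(mesh$chains$fat_inner, mesh$sets$wall, mesh$sets$free,
                 mesh$chains$fat_wall,
                 which(abs(mesh$nodes[, 2] - min(mesh$nodes[, 2])) < 1e-9)))
  ctx$fixed <- sort(unique(c(ctx$fixed, 2 * bd - 1L, 2 * bd)))
  eps <- 0.01
  st <- ns$newton_solve(ctx, numeric(ctx$ndof),
                        list(eps_v = 0, eps_fat = eps, ICP = 0, M = 0, IOP = 0))
  expect_true(st$converged)
  ef <- element_fields(mesh, tissue_registry(), st$u, eps_fat = eps)
  JH <- (1 + eps)^3
  kap <- tissue_registry()$kappa[3]
  expect_equal(unname(ef[, "Je"]), rep(1 / JH, nrow(ef)), tolerance = 1e-3)
  expect_equal(unname(ef[, "hydro"]), rep(kap * (1 - JH) / JH, nrow(ef)),
               tolerance = 0.02 * kap * (JH - 1) / JH)
})

test_that("contact transfers no tangential traction and no penetration", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_geometry(geom, "coarse", 2)
  ci <- contact_interface(mesh)
  expect_true(all(ci$tangential == 0))
  expect_gt(min(ci$gap, na.rm = TRUE), -1e-3) # 1 um penetration budget
})

test_that("an empty continuation schedule returns an empty list", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_eye(geom, "coarse", 2)
  ns <- asNamespace("orbitfem")
  ctx <- ns$solve_context(mesh, tissue_registry(), load_case(), stage = "eye")
  out <- ns$step_continuation(ctx, data.frame())
  expect_identical(out, list())
})

test_that("a non-convergent step reports the load fraction reached", {
  geom <- build_anatomy(anatomy_params())
  mesh <- mesh_eye(geom, "coarse", 2)
  ns <- asNamespace("orbitfem")
  ctx <- ns$solve_context(mesh, tissue_registry(), load_case(), stage = "eye")
  # an absurd single step (300% vitreous swelling) cannot converge
  sch <- data.frame(eps_v = 3, eps_fat = 0, ICP = 0, M = 0, IOP = 0)
  err <- tryCatch(ns$step_continuation(ctx, sch, max_bisect = 0),
                  error = function(e) e)
  expect_s3_class(err, "orbitfem_nonconvergence")
  expect_match(conditionMessage(err), "0 steps completed")
})
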