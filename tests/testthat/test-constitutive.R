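# Material model: swelling arithmetic, stress/tangent consistency,
# frame indifference, closed-form uniaxial response.

test_that("hygroscopic state reproduces the printed volume ratios", {
  # the baseline schedule column, read as strain via beta = 0.001 m^3/kg
  eps <- c(0, 0.010, 0.015, 0.020, 0.025, 0.030, 0.035, 0.040, 0.045,
           0.050, 0.055, 0.060, 0.065, 0.070)
  JH_printed <- c(1.000, 1.030, 1.046, 1.061, 1.077, 1.093, 1.109, 1.125,
                  1.141, 1.158, 1.174, 1.191, 1.208, 1.225)
  st <- swelling_from_strain(eps)
  expect_equal(st$eps_H, eps)
  expect_equal(round(st$J_H, 3), JH_printed)
  expect_equal(hygroscopic_state(C_W = 70, C_W0 = 0, beta = 1e-3)$eps_H, 0.070)
  expect_equal(hygroscopic_state(C_W = 5, C_W0 = 5)$J_H, 1)
  expect_error(hygroscopic_state(C_W = -2000, C_W0 = 0), "collapse")
  expect_error(hygroscopic_state(1, beta = 0), "beta")
})

test_that("stress vanishes in the reference and isotropically swollen states", {
  s0 <- strain_energy(diag(3), mu = 500, kappa = 5e6, J_H = 1)
  expect_equal(max(abs(s0$P)), 0, tolerance = 1e-9)
  expect_equal(s0$W, 0, tolerance = 1e-12)
  for (JH in c(1.05, 1.225)) {
    sw <- strain_energy(JH^(1 / 3) * diag(3), mu = 233, kappa = 2e6, J_H = JH)
    expect_equal(max(abs(sw$P)), 0, tolerance = 1e-6)
  }
})

test_that("stress is the derivative of the energy (finite differences)", {
  set.seed(42)
  for (k in 1:4) {
    F <- diag(3)
    F[1, 1] <- 1 + rnorm(1, 0, 0.1)
    F[2, 2] <- 1 + rnorm(1, 0, 0.1)
    F[3, 3] <- 1 + rnorm(1, 0, 0.1)
    F[1, 2] <- rnorm(1, 0, 0.1)
    F[2, 1] <- rnorm(1, 0, 0.1)
    mu <- 5e5; kap <- 5e8; JH <- 1.08
    s <- strain_energy(F, mu, kap, JH)
    h <- 1e-6
    for (ij in list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 3))) {
      Fp <- F; Fp[ij[1], ij[2]] <- Fp[ij[1], ij[2]] + h
      Fm <- F; Fm[ij[1], ij[2]] <- Fm[ij[1], ij[2]] - h
      fd <- (strain_energy(Fp, mu, kap, JH)$W -
               strain_energy(Fm, mu, kap, JH)$W) / (2 * h)
      expect_equal(s$P[ij[1], ij[2]], fd, tolerance = 1e-5)
    }
  }
})

test_that("energy is frame indifferent under random rotations", {
  set.seed(7)
  F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  if (det(F) <= 0) F <- diag(3) + 0.05
  W0 <- strain_energy(F, 700, 2e6, 1.1)$W
  for (k in 1:5) {
    th <- runif(1, 0, 2 * pi)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_equal(strain_energy(R %*% F, 700, 2e6, 1.1)$W, W0,
                 tolerance = 1e-8 * max(W0, 1))
  }
})

test_that("uniaxial incompressible response matches mu (lambda - lambda^-2)", {
  mu <- 1.5e6 / 3
  kap <- 1e4 * mu
  lam <- 1.1
  # find the lateral stretch that annuls the transverse stress
  f <- function(a) strain_energy(diag(c(lam, a, a)), mu, kap)$P[2, 2]
  a <- uniroot(f, c(0.8, 1.1), tol = 1e-12)$root
  P11 <- strain_energy(diag(c(lam, a, a)), mu, kap)$P[1, 1]
  expect_equal(P11, mu * (lam - lam^-2), tolerance = 2e-3 * mu)
  # and volume is preserved to the penalty tolerance
  expect_equal(lam * a^2, 1, tolerance = 1e-3)
})

test_that("tissue registry holds the baseline moduli", {
  reg <- tissue_registry()
  expect_equal(reg$E[reg$name == "ocular_coats"], 1.5e6)
  expect_equal(reg$E[reg$name == "vitreous"], 6.5)
  expect_equal(reg$E[reg$name == "orbital_fat"], 700)
  expect_true(reg$rigid[reg$name == "orbital_bone"])
  expect_true(all(reg$incompressible))
  expect_equal(reg$mu, reg$E / 3)
  expect_error(tissue_registry(E_fat = -1))
})
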