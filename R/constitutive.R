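#' Baseline tissue-property registry
#'
#' Elastic moduli of the modelled tissues. All soft tissues are treated as
#' incompressible, isotropic, neo-Hookean; the orbital bone is rigid and enters
#' the model only as a fixed boundary. The shear modulus is derived as
#' `mu = E / 3` (incompressible limit) and incompressibility is enforced by a
#' volumetric penalty `kappa = max(1e4 * mu, kappa_floor)`.
#'
#' @param E_sclera,E_vitreous,E_fat,E_bundle,E_dura elastic moduli in Pa.
#'   Defaults: ocular coats 1.5 MPa, vitreous humour 6.5 Pa, orbital fat 700 Pa.
#'   The optic-nerve tissues carry no published value in the source tables;
#'   the dural sheath is given the scleral modulus (it is continuous with the
#'   sclera) and the axon bundle 30 kPa, a literature-order value for neural
#'   tissue.
#' @param kappa_floor lower bound on the volumetric penalty modulus (Pa). The
#'   floor keeps the elastic volume error `|J/J_H - 1| = p/kappa` below 1e-3
#'   for the near-fluid tissues whose shear moduli are only a few Pa.
#' @param kappa_ratio penalty-to-shear ratio for the stiffer tissues.
#' @return a `tissue_registry`: data.frame with one row per tissue
#'   (name, E, mu, kappa, incompressible, rigid).
#' @export
tissue_registry <- function(E_sclera = 1.5e6, E_vitreous = 6.5, E_fat = 700,
                            E_bundle = 3e4, E_dura = E_sclera,
                            kappa_floor = 5e6, kappa_ratio = 1e3) {
  E <- c(ocular_coats = E_sclera, vitreous = E_vitreous, orbital_fat = E_fat,
         axon_bundle = E_bundle, dura = E_dura)
  if (any(!is.finite(E)) || any(E <= 0))
    stop("tissue_registry: all elastic moduli must be positive and finite")
  mu <- E / 3
  reg <- data.frame(
    name = names(E), E = unname(E), mu = unname(mu),
    kappa = pmax(kappa_ratio * unname(mu), kappa_floor),
    incompressible = TRUE, rigid = FALSE,
    stringsAsFactors = FALSE
  )
  reg <- rbind(reg, data.frame(name = "orbital_bone", E = Inf, mu = Inf,
                               kappa = Inf, incompressible = TRUE, rigid = TRUE))
  class(reg) <- c("tissue_registry", "data.frame")
  reg
}

#' Hygroscopic swelling state
#'
#' Swelling is driven by added water content: the hygroscopic strain is
#' `eps_H = beta * (C_W - C_W0)` and the stress-free volume ratio
#' `J_H = (1 + eps_H)^3`. With `beta = 0.001` m^3/kg (inverse density of
#' water), a water-content increment quoted in kg/m^3 divided by 1000 equals
#' the strain itself; swelling schedules in this package are therefore stated
#' directly as `eps_H`.
#'
#' @param C_W current water content (kg/m^3).
#' @param C_W0 baseline water content (kg/m^3).
#' @param beta coefficient of hygroscopic swelling (m^3/kg), default 0.001.
#' @return a `swelling_state` list with `beta, C_W, C_W0, eps_H, J_H`.
#' @examples
#' hygroscopic_state(C_W = 70, C_W0 = 0)$J_H # (1 + 0.070)^3 = 1.225043
#' @export
hygroscopic_state <- function(C_W, C_W0 = 0, beta = 1e-3) {
  if (!is.finite(beta) || beta <= 0) stop("hygroscopic_state: beta must be > 0")
  eps_H <- beta * (C_W - C_W0)
  if (any(eps_H <= -1))
    stop("hygroscopic_state: eps_H <= -1 (non-physical collapse)")
  out <- list(beta = beta, C_W = C_W, C_W0 = C_W0,
              eps_H = eps_H, J_H = (1 + eps_H)^3)
  class(out) <- "swelling_state"
  out
}

#' Swelling state from a hygroscopic strain
#'
#' Convenience constructor when the schedule is stated as strain values.
#' @param eps_H hygroscopic strain (dimensionless).
#' @inheritParams hygroscopic_state
#' @return a `swelling_state` (see [hygroscopic_state()]).
#' @export
swelling_from_strain <- function(eps_H, beta = 1e-3) {
  hygroscopic_state(C_W = eps_H / beta, C_W0 = 0, beta = beta)
}

#' Neo-Hookean strain energy and first Piola-Kirchhoff stress at a point
#'
#' Evaluates the nearly incompressible neo-Hookean model with multiplicative
#' hygroscopic swelling `F = F_e * J_H^(1/3) I`:
#' `W = J_H * ( mu/2 (J^{-2/3} I1 - 3) + kappa/2 ln(J/J_H)^2 )`.
#' The stress-free state is the isotropically swollen configuration
#' `F = J_H^(1/3) I`. Used mainly for verification; the assembled FE kernel
#' evaluates the same expressions in compiled code.
#'
#' @param F deformation gradient, 3x3 matrix with `det(F) > 0`. For
#'   axisymmetric states only the upper-left 2x2 block and `F[3,3]` (hoop
#'   stretch) may differ from the identity.
#' @param mu shear modulus (Pa).
#' @param kappa volumetric penalty modulus (Pa).
#' @param J_H hygroscopic volume ratio (default 1).
#' @return list with `W` (energy density, Pa), `P` (first Piola stress, 3x3),
#'   `sigma` (Cauchy stress, 3x3).
#' @export
strain_energy <- function(F, mu, kappa, J_H = 1) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("strain_energy: non-positive Jacobian (element inversion)")
  if (max(abs(F[1, 3]), abs(F[2, 3]), abs(F[3, 1]), abs(F[3, 2])) > 1e-12) {
    # general 3x3 path (used for frame-indifference checks)
    I1 <- sum(F * F)
    Finv <- solve(F)
    L <- log(J / J_H)
    W <- J_H * (mu / 2 * (J^(-2 / 3) * I1 - 3) + kappa / 2 * L^2)
    P <- J_H * (mu * J^(-2 / 3) * (F - I1 / 3 * t(Finv)) + kappa * L * t(Finv))
  } else {
    f <- c(F[1, 1], F[1, 2], F[2, 1], F[2, 2], F[3, 3])
    pw <- nh_point(f, mu, kappa, J_H)
    W <- pw$W
    P <- matrix(0, 3, 3)
    P[1, 1] <- pw$P[1]; P[1, 2] <- pw$P[2]
    P[2, 1] <- pw$P[3]; P[2, 2] <- pw$P[4]; P[3, 3] <- pw$P[5]
  }
  sigma <- P %*% t(F) / J
  list(W = W, P = P, sigma = sigma, J = J, J_e = J / J_H)
}
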