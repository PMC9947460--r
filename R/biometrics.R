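# Ocular biometric outputs: proptosis, axial length, peripapillary arc length,
# posterior radius of curvature, and the axial force-balance report.

# deformed sample points along a set of chain edges (edge basis interpolation)
sample_edges <- function(mesh, edges, u, n_per_edge = 8) {
  p <- mesh$order
  xi <- seq(0, 1, length.out = n_per_edge)
  eb <- edge_basis_eval(p, xi)
  out <- vector("list", ncol(edges))
  for (k in seq_len(ncol(edges))) {
    ids <- edges[, k]
    xr <- mesh$nodes[ids, 1] + u[2 * ids - 1]
    xz <- mesh$nodes[ids, 2] + u[2 * ids]
    out[[k]] <- cbind(as.numeric(crossprod(eb$phi, xr)),
                      as.numeric(crossprod(eb$phi, xz)))
  }
  do.call(rbind, out)
}

# arc length of chain edges in the deformed configuration (5-pt Gauss)
chain_arclength <- function(mesh, edges, u) {
  p <- mesh$order
  g <- gauss1d(5)
  eb <- edge_basis_eval(p, g$x)
  total <- 0
  for (k in seq_len(ncol(edges))) {
    ids <- edges[, k]
    xr <- mesh$nodes[ids, 1] + u[2 * ids - 1]
    xz <- mesh$nodes[ids, 2] + u[2 * ids]
    dr <- crossprod(eb$dphi, xr)
    dz <- crossprod(eb$dphi, xz)
    total <- total + sum(g$w * sqrt(dr^2 + dz^2))
  }
  total
}

#' Posterior radius of curvature by Pratt circle fit
#'
#' Samples the deformed outer scleral surface within a radial window of the
#' symmetry axis (default 4 mm, evaluated in the deformed configuration) and
#' fits a circle by the Pratt method. At least 50 uniformly spaced sample
#' points are used so the fit does not depend on mesh nodes.
#'
#' @param mesh a `mesh_model` containing the eye.
#' @param u displacement vector (0 for the reference state).
#' @param window radial window (mm).
#' @param reference_window if `TRUE`, select points by their reference radius
#'   instead of the deformed radius.
#' @return fitted radius (mm).
#' @export
posterior_roc <- function(mesh, u = numeric(2 * nrow(mesh$nodes)),
                          window = 4, reference_window = FALSE) {
  ed <- mesh$chain_edges$outer_sclera
  th <- mesh$sets$outer_theta
  # posterior edges only: both end parameters beyond the equator
  thc <- matrix(th[match(ed, mesh$chains$outer_sclera)], nrow(ed), ncol(ed))
  keep <- thc[1, ] > pi / 2 & thc[nrow(ed), ] > pi / 2
  ed <- ed[, keep, drop = FALSE]
  if (ncol(ed) == 0) stop("posterior_roc: no posterior surface edges")
  npe <- max(8, ceiling(150 / ncol(ed)))
  pts <- sample_edges(mesh, ed, u, n_per_edge = npe)
  rsel <- if (reference_window)
    sample_edges(mesh, ed, numeric(length(u)), n_per_edge = npe)[, 1]
  else pts[, 1]
  pts <- pts[rsel <= window, , drop = FALSE]
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 3)
    stop("posterior_roc: fewer than 3 surface points in the window; ",
         "refine the surface sampling")
  pratt_circle_fit(pts)$radius
}

#' Peripapillary arc length
#'
#' Arc length (meridian plane) of the fixed material segment of the inner
#' sclera spanning the posterior-most fraction of the eye's circumference,
#' labelled in the zero-stress state. The default fraction 1/4 corresponds to
#' polar angles within 45 degrees of the posterior pole; the segment ends at
#' the scleral canal.
#'
#' @param mesh eye or combined `mesh_model` (labels from its zero-stress
#'   reference configuration).
#' @param u displacement vector.
#' @param fraction of the circumference (1/8, 1/4 or 1/2).
#' @return arc length in mm.
#' @export
peripapillary_arc <- function(mesh, u = numeric(2 * nrow(mesh$nodes)),
                              fraction = 1 / 4) {
  th0 <- pi - fraction * pi
  ed <- mesh$chain_edges$inner_sclera
  if (is.null(ed)) stop("peripapillary_arc: mesh lacks inner-sclera labels")
  thc <- matrix(mesh$sets$inner_theta[match(ed, mesh$chains$inner_sclera)],
                nrow(ed), ncol(ed))
  keep <- thc[1, ] >= th0 - 1e-9 & thc[nrow(ed), ] >= th0 - 1e-9
  ed <- ed[, keep, drop = FALSE]
  if (ncol(ed) == 0) stop("peripapillary_arc: no labelled segment in range")
  chain_arclength(mesh, ed, u)
}

#' Proptosis and axial-length change between two states
#'
#' Proptosis is the anterior-pole axial displacement (state D minus state C);
#' the axial length is measured on the axis from the anterior outer pole to
#' the disc centre (the posterior outer pole is occupied by the scleral
#' canal).
#'
#' @param mesh `mesh_model` containing the eye.
#' @param uD,uC displacement vectors of the two states.
#' @return list with `proptosis_mm` and `dAL_um`.
#' @export
axial_measures <- function(mesh, uD, uC) {
  ap <- mesh$sets$anterior_pole
  dc <- mesh$sets$disc_center
  al <- function(u) (mesh$nodes[ap, 2] + u[2 * ap]) - (mesh$nodes[dc, 2] + u[2 * dc])
  list(proptosis_mm = uD[2 * ap] - uC[2 * ap],
       dAL_um = (al(uD) - al(uC)) * 1000)
}

#' Axial force balance of a converged state
#'
#' Axial resultants on the eye/nerve assembly: ICP band traction and fat
#' contact push anteriorly; muscle tension and the nerve spring pull
#' posteriorly. At equilibrium the residual
#' `F_ICP + F_fat - F_EOM - F_ON` vanishes to solver tolerance.
#'
#' @param state a solution state from the protocol or [solve_equilibrium()].
#' @return list of the four resultants (mN) and the residual.
#' @export
force_balance <- function(state) {
  f <- state$forces
  f <- lapply(f, function(x) if (is.null(x) || length(x) == 0) 0 else x)
  resid <- f$F_ICP + f$F_fat - f$F_EOM - f$F_ON
  c(f, list(residual = resid))
}

# biometric report of a D state relative to the C state
biometric_row <- function(mesh, uD, uC, eps_fat, pars, state) {
  ax <- axial_measures(mesh, uD, uC)
  arcD <- peripapillary_arc(mesh, uD)
  arcC <- peripapillary_arc(mesh, uC)
  rocD <- posterior_roc(mesh, uD)
  rocC <- posterior_roc(mesh, uC)
  fb <- force_balance(state)
  data.frame(eps_H_fat = eps_fat, J_H = (1 + eps_fat)^3,
             proptosis_mm = ax$proptosis_mm, dAL_um = ax$dAL_um,
             darc_um = (arcD - arcC) * 1000, dROC_mm = rocD - rocC,
             F_EOM_mN = fb$F_EOM, F_ICP_mN = fb$F_ICP, F_fat_mN = fb$F_fat,
             F_ON_mN = fb$F_ON, balance_residual_mN = fb$residual,
             ICP_cmH2O = pars$ICP, M = pars$M)
}
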