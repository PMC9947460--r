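#' Build the axisymmetric geometry model
#'
#' Derives the named 2-D regions of the (r, z) half-plane (ocular coats,
#' vitreous, orbital fat, axon bundle, dura) and the named boundaries (axis,
#' orbit wall, orbit margin free surface, sclera surfaces, sub-arachnoid ICP
#' band, EOM insertion ring, nerve apex) from an [anatomy_params()] set.
#'
#' Coordinates: `z` is the symmetry/optical axis, positive anterior, with the
#' orbital apex at `z = 0`; `r >= 0` is the radial coordinate. The globe
#' centre sits at `z_c = L_O - L_OM`. The scleral shell terminates at the
#' scleral canal (`r = R_A`); the axon bundle runs from the disc to the apex,
#' the dural sheath (`R_Di..R_Do`) hangs from the posterior shell, and the
#' sub-arachnoid gap between them is a void. Orbital fat fills the space
#' between globe/nerve and the rigid orbit wall, with a free (traction-free)
#' annular surface at the rim plane `z = L_O`.
#'
#' @param params an [anatomy_params()] object.
#' @param insertion_theta polar angle (from the anterior pole, rad) of the EOM
#'   insertion ring on the outer shell surface.
#' @param orbit_bulge interior widening of the orbit: the wall's widest point
#'   (at depth `L_OM` behind the rim) has radius `orbit_bulge * R_OM`. The
#'   orbital cavity is widest a short distance behind the rim; a straight
#'   apex-to-rim cone would leave the globe tangent to the bone with no fat
#'   channel, and could not contain a globe whose equatorial diameter exceeds
#'   the rim aperture.
#' @return a `geometry_model` with derived scalars, parametric curves and
#'   region polygon samplers.
#' @export
build_anatomy <- function(params, insertion_theta = pi / 3, orbit_bulge = 1.1,
                          globe_centre = getOption("orbitfem.globe_centre", "rim")) {
  validate_anatomy(params)
  p <- params
  a_i <- p$R_Eq; b_i <- p$R_P
  a_o <- p$R_Eq + p$h_Eq; b_o <- p$R_P + p$h_P
  # globe centre at the orbital rim plane (the posterior half of the globe
  # sits in the orbit; apex-to-centre distance = L_O - AL/2). If the equator
  # is wider than the rim aperture the globe shifts anteriorly until it
  # clears the rim by a small margin.
  g_rim <- 0.6
  zc <- if (identical(globe_centre, "margin")) p$L_O - p$L_OM else p$L_O
  if (a_o > p$R_OM - g_rim && zc >= p$L_O)
    zc <- p$L_O + b_o * sqrt(1 - ((p$R_OM - g_rim) / a_o)^2)
  sas_mm <- p$sas_band / 1000

  ell_in <- function(th) cbind(a_i * sin(th), zc + b_i * cos(th))
  ell_out <- function(th) cbind(a_o * sin(th), zc + b_o * cos(th))
  z_out_r <- function(r) zc - b_o * sqrt(pmax(1 - (r / a_o)^2, 0))
  z_in_r <- function(r) zc - b_i * sqrt(pmax(1 - (r / a_i)^2, 0))

  theta_cut <- pi - asin(p$R_A / a_i)          # shell terminates (canal)
  theta_RDi <- pi - asin(p$R_Di / a_o)          # dura inner attach (outer surf)
  theta_RDo <- pi - asin(p$R_Do / a_o)          # dura outer attach
  theta_sas1 <- pi - asin((p$R_Do + sas_mm) / a_o) # anterior edge of ICP band
  if (!(theta_sas1 < theta_RDo && theta_RDo < theta_RDi && theta_RDi < theta_cut))
    stop("build_anatomy: posterior-pole features overlap ",
         "(sas band / dura / canal ordering violated)")
  # rim-plane intersection of the outer globe (anterior end of the fat)
  cth_exit <- (p$L_O - zc) / b_o
  theta_exit <- acos(pmin(pmax(cth_exit, -1), 1))
  r_exit <- a_o * sin(theta_exit)
  if (r_exit >= p$R_OM)
    stop("build_anatomy: globe fills the orbit margin completely")

  R_W <- orbit_bulge * p$R_OM
  z_w <- p$L_O - p$L_OM # widest point, L_OM behind the rim
  wall <- rbind(c(p$R_Do, 0), c(R_W, z_w), c(p$R_OM, p$L_O))
  wall_r <- function(z) ifelse(z <= z_w,
                               p$R_Do + (R_W - p$R_Do) * z / z_w,
                               R_W + (p$R_OM - R_W) * (z - z_w) / (p$L_O - z_w))
  # the fat channel between globe and wall must not pinch off
  zchk <- seq(0.05 * zc, p$L_O, length.out = 400)
  gchk <- wall_r(zchk) - pmax(a_o * sqrt(pmax(1 - ((zchk - zc) / b_o)^2, 0)),
                              ifelse(zchk < zc - b_o, p$R_Do, 0))
  if (min(gchk) < 0.2)
    stop("build_anatomy: orbital wall touches the globe ",
         "(fat channel pinched off; min gap ", round(min(gchk), 3), " mm)")

  curves <- list(
    inner_ell = function(th) ell_in(th),
    outer_ell = function(th) ell_out(th)
  )

  # region polygon samplers (dense, for areas / tiling checks / plots)
  n <- 200
  th_sh <- seq(0, theta_cut, length.out = n)
  poly_coats <- rbind(ell_out(rev(th_sh)),
                      cbind(p$R_A, seq(z_out_r(p$R_A), z_in_r(p$R_A), length.out = 5)),
                      ell_in(th_sh))
  th_v <- seq(0, pi, length.out = 2 * n)
  poly_vitreous <- ell_in(th_v) # closed by the axis segment
  poly_vitreous <- rbind(poly_vitreous, c(0, zc - b_i), c(0, zc + b_i))
  rb <- seq(0, p$R_A, length.out = n)
  poly_bundle <- rbind(cbind(rb, z_in_r(rb)), c(p$R_A, 0), c(0, 0))
  rd <- seq(p$R_Di, p$R_Do, length.out = n)
  poly_dura <- rbind(cbind(rd, z_out_r(rd)), c(p$R_Do, 0), c(p$R_Di, 0))
  th_f <- seq(theta_RDo, theta_exit, length.out = 2 * n) # decreasing angles
  poly_fat <- rbind(c(p$R_Do, 0),
                    c(p$R_Do, z_out_r(p$R_Do)),
                    ell_out(th_f),
                    c(p$R_OM, p$L_O),
                    c(R_W, z_w),
                    c(p$R_Do, 0))

  regions <- list(ocular_coats = poly_coats, vitreous = poly_vitreous,
                  orbital_fat = poly_fat, axon_bundle = poly_bundle,
                  dura = poly_dura)
  areas <- vapply(regions, polygon_area, numeric(1))
  if (any(areas <= 0)) stop("build_anatomy: degenerate region polygon")

  out <- list(params = p, zc = zc, a_i = a_i, b_i = b_i, a_o = a_o, b_o = b_o,
              theta_cut = theta_cut, theta_RDi = theta_RDi,
              theta_RDo = theta_RDo, theta_sas1 = theta_sas1,
              theta_exit = theta_exit, r_exit = r_exit,
              insertion_theta = insertion_theta, wall = wall, wall_r = wall_r,
              orbit_bulge = orbit_bulge,
              curves = curves, z_out_r = z_out_r, z_in_r = z_in_r,
              regions = regions, areas = areas)
  class(out) <- "geometry_model"
  out
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' @exportS3Method base::print
print.geometry_model <- function(x, ...) {
  cat("<geometry_model>\n")
  cat(sprintf("  globe centre z_c = %.3f mm; outer semi-axes (%.3f, %.3f) mm\n",
              x$zc, x$a_o, x$b_o))
  cat("  meridian region areas (mm^2):\n")
  print(round(x$areas, 3))
  invisible(x)
}

#' Deterministic hash of a geometry model
#'
#' Identical parameters produce identical geometry; the hash covers the
#' parameter set and all derived polygons.
#' @param geom a `geometry_model`.
#' @return character scalar.
#' @export
geometry_hash <- function(geom) {
  rlang::hash(list(geom$params, geom$regions, geom$insertion_theta))
}
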