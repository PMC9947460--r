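#' Passive extraocular-muscle tension law
#'
#' Resultant axial tension of the four rectus muscles as a function of the
#' anterior displacement `w` (mm) of the insertion ring:
#' `F_EOM = 4 M (-0.29 w + 4.79 exp(w / 4.57) - 3.01)` in mN.
#' `M = 1` is the passive muscle; `M` up to 2.25 emulates an active
#' contribution that roughly doubles the peak force.
#'
#' @param w anterior displacement of the insertion point (mm); vectorised.
#' @param M dimensionless multiplier, `M >= 0`.
#' @return force in mN (positive = posteriorly directed pull).
#' @examples
#' eom_force(0, 1) # 4 * (4.79 - 3.01) = 7.12 mN
#' @export
eom_force <- function(w, M = 1) {
  stopifnot(all(M >= 0))
  4 * M * (-0.29 * w + 4.79 * exp(w / 4.57) - 3.01)
}

# derivative dF/dw (mN per mm), used in the consistent tangent
eom_force_dw <- function(w, M = 1) {
  4 * M * (-0.29 + 4.79 / 4.57 * exp(w / 4.57))
}

#' Insertion displacement that produces a given muscle force
#'
#' Inverts [eom_force()] in `w` by scalar root finding.
#' @param F target force (mN).
#' @param M multiplier.
#' @return displacement `w` in mm.
#' @export
eom_w_from_force <- function(F, M = 1) {
  uniroot(function(w) eom_force(w, M) - F, c(-5, 60), tol = 1e-10)$root
}

#' Optic-nerve slack
#'
#' Signed slack of the optic nerve:
#' `slack = ON length - orbit length - axial length / 2` (all mm).
#' The nerve carries no load until anterior translation of the globe exceeds
#' the slack.
#'
#' @param on_length optic-nerve length (mm).
#' @param orbit_length orbit length (mm).
#' @param axial_length globe axial length (mm).
#' @return slack in mm (may be negative).
#' @export
on_slack <- function(on_length, orbit_length, axial_length) {
  stopifnot(all(on_length > 0), all(orbit_length > 0), all(axial_length > 0))
  on_length - orbit_length - axial_length / 2
}

#' Optic-nerve spring force
#'
#' Tension develops only once the anterior translation of the globe exceeds
#' the slack; the response is linear beyond the threshold and continuous at it.
#'
#' @param anterior_translation anterior translation of the globe (mm).
#' @param slack slack threshold (mm), default 6.
#' @param k spring stiffness (N/m). 1 N/m * 1 mm = 1 mN.
#' @return force in mN (posteriorly directed tension).
#' @export
on_spring_force <- function(anterior_translation, slack = 6, k = 1) {
  stopifnot(k >= 0)
  pmax(anterior_translation - slack, 0) * k
}

#' Define a load case
#'
#' Bundles every boundary load of the model: target IOP (produced by vitreous
#' swelling unless `iop_mode = "direct"`), intracranial pressure applied as a
#' normal traction over the sub-arachnoid band of the posterior sclera, the
#' extraocular-muscle multiplier, the fat-swelling schedule and the
#' optic-nerve slack spring.
#'
#' @param IOP_target target intraocular pressure (mmHg). The source model
#'   never prints its value; 15 mmHg (mid-normal) is the package default.
#' @param ICP intracranial pressure (cmH2O) in the swollen (microgravity)
#'   state; the terrestrial stage always uses `ICP_terrestrial`.
#' @param ICP_terrestrial terrestrial ICP (cmH2O), default 13.6 (= 10 mmHg).
#' @param M extraocular-muscle multiplier in `[0, 2.25]`.
#' @param eps_H_fat non-decreasing, non-negative schedule of fat hygroscopic
#'   strains; defaults to the baseline study schedule 0, 0.010, 0.015, ... 0.070.
#' @param on_slack_threshold optic-nerve slack (mm), default 6.
#' @param on_spring_stiffness spring stiffness beyond slack (N/m), default 1.
#'   Irrelevant whenever translation stays below the slack, but finite for
#'   robustness.
#' @param iop_mode `"swelling"` (vitreous hygroscopic swelling generates IOP;
#'   the reference method) or `"direct"` (pressure boundary condition on the
#'   inner shell surface; diagnostic mode).
#' @param icp_band where the intracranial pressure acts: `"sas_roof"`
#'   (default) loads the scleral flange face over the sub-arachnoid space,
#'   whose projected annulus `pi (R_Di^2 - R_A^2)` reproduces the quoted
#'   terrestrial resultant of about 1.2 mN at 13.6 cmH2O;
#'   `"outer_annulus"` loads a 270-um-wide ring of the outer sclera starting
#'   at the outer dural radius.
#' @param insertion_theta polar angle of the EOM insertion ring measured from
#'   the anterior pole (rad); default `pi/3`, anterior to the equator.
#' @return a `load_case` list.
#' @export
load_case <- function(IOP_target = 15, ICP = 13.6, ICP_terrestrial = 13.6,
                      M = 1,
                      eps_H_fat = c(0, seq(0.010, 0.070, by = 0.005)),
                      on_slack_threshold = 6, on_spring_stiffness = 1,
                      iop_mode = c("swelling", "direct"),
                      insertion_theta = pi / 3,
                      icp_band = c("sas_roof", "outer_annulus")) {
  iop_mode <- match.arg(iop_mode)
  icp_band <- match.arg(icp_band)
  if (ICP < 0 || ICP > 40 || ICP_terrestrial < 0 || ICP_terrestrial > 40)
    stop("load_case: ICP must lie in [0, 40] cmH2O")
  if (M < 0 || M > 2.25)
    stop("load_case: M must lie in [0, 2.25]")
  if (length(eps_H_fat) > 0) {
    if (any(eps_H_fat < 0) || is.unsorted(eps_H_fat))
      stop("load_case: eps_H_fat must be non-negative and non-decreasing")
  }
  out <- list(IOP_target = IOP_target, ICP = ICP,
              ICP_terrestrial = ICP_terrestrial, M = M,
              eps_H_fat = eps_H_fat,
              on_slack_threshold = on_slack_threshold,
              on_spring_stiffness = on_spring_stiffness,
              iop_mode = iop_mode, insertion_theta = insertion_theta,
              icp_band = icp_band)
  class(out) <- "load_case"
  out
}

#' @exportS3Method base::print
print.load_case <- function(x, ...) {
  cat("<load_case>\n")
  cat(sprintf("  IOP target     : %g mmHg (%s mode)\n", x$IOP_target, x$iop_mode))
  cat(sprintf("  ICP            : %g cmH2O (terrestrial %g)\n", x$ICP, x$ICP_terrestrial))
  cat(sprintf("  EOM multiplier : %g\n", x$M))
  cat(sprintf("  fat eps_H      : %s\n", paste(format(x$eps_H_fat), collapse = ", ")))
  cat(sprintf("  ON slack       : %g mm, k = %g N/m\n",
              x$on_slack_threshold, x$on_spring_stiffness))
  invisible(x)
}

#' Intracranial-pressure band traction
#'
#' Computes the normal traction magnitude and the analytic axial resultant of
#' ICP applied over the sub-arachnoid band: the annulus of the posterior
#' sclera of radial extent `sas_band` starting at the outer dural radius.
#' The axial resultant equals pressure times projected annular area,
#' `F = p * pi * ((R_Do + b)^2 - R_Do^2)`, linear in ICP at fixed geometry.
#' The FE solver applies the same traction as a follower load over the tagged
#' band; this closed form is its quadrature cross-check.
#'
#' @param ICP intracranial pressure (cmH2O).
#' @param geom a `geometry_model` from [build_anatomy()].
#' @return list with `pressure_Pa`, `band` (inner/outer radius, mm) and
#'   `axial_resultant_mN`.
#' @export
icp_traction <- function(ICP, geom, icp_band = c("sas_roof", "outer_annulus")) {
  stopifnot(ICP >= 0)
  icp_band <- match.arg(icp_band)
  p <- pressure_convert(ICP, "cmH2O", "Pa")
  pr <- geom$params
  if (is.null(pr$R_Do) || is.null(pr$sas_band))
    stop("icp_traction: geometry lacks a sub-arachnoid band configuration")
  if (icp_band == "sas_roof") {
    r0 <- geom$a_o * sin(pi - geom$theta_cut) # canal edge on the outer surface
    r1 <- pr$R_Di
  } else {
    r0 <- pr$R_Do
    r1 <- pr$R_Do + pr$sas_band / 1000
  }
  area_mm2 <- pi * (r1^2 - r0^2)
  list(pressure_Pa = p, band = c(inner = r0, outer = r1),
       axial_resultant_mN = p * area_mm2 * 1e-3)
}
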