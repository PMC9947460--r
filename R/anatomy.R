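#' Anatomical parameters of the axisymmetric eye/orbit model
#'
#' The twelve geometric scalars defining the axisymmetric eye, orbit, optic
#' nerve and dural sheath. Defaults are the baseline (normal human) values.
#' The globe's inner surface is the ellipse with semi-axes `(R_Eq, R_P)`; the
#' outer surface is the ellipse with semi-axes `(R_Eq + h_Eq, R_P + h_P)`, so
#' shell thickness blends smoothly and monotonically from `h_P` at the poles
#' to `h_Eq` at the equator. The orbit wall is two straight segments built
#' from the printed scalars: apex `(R_Do, 0)` to the wide point
#' `(R_OM, L_O - L_OM)` and on to the rim `(R_OM, L_O)`; the globe centre sits
#' at `z = L_O - L_OM` so its equator lies in the wide-point plane.
#'
#' @param R_Eq equatorial (inner) radius, mm.
#' @param R_P polar (inner) radius, mm; axial length = `2 R_P`.
#' @param h_Eq equatorial shell thickness, mm.
#' @param h_P polar shell thickness, mm.
#' @param R_OM orbit margin radius, mm.
#' @param L_OM orbit margin length (rim plane to globe equator plane), mm.
#' @param L_O total orbit length, mm.
#' @param R_A radius of the axon bundle, mm.
#' @param R_Di inner radius of the dura, mm.
#' @param R_Do outer radius of the dura, mm.
#' @param sas_band radial extent of the sub-arachnoid ICP band, micrometres.
#' @return an `anatomy_params` list (validated).
#' @export
anatomy_params <- function(R_Eq = 12.36, R_P = 12.36, h_Eq = 0.5, h_P = 1.0,
                           R_OM = 13.95, L_OM = 9.51, L_O = 40.26,
                           R_A = 0.85, R_Di = 1.0, R_Do = 1.515,
                           sas_band = 270) {
  p <- list(R_Eq = R_Eq, R_P = R_P, h_Eq = h_Eq, h_P = h_P, R_OM = R_OM,
            L_OM = L_OM, L_O = L_O, R_A = R_A, R_Di = R_Di, R_Do = R_Do,
            sas_band = sas_band)
  validate_anatomy(p)
  class(p) <- "anatomy_params"
  p
}

validate_anatomy <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("anatomy_params: all lengths must be strictly positive ",
         "(violated by: ", paste(names(num)[!is.finite(num) | num <= 0],
                                 collapse = ", "), ")")
  if (p$R_Di <= p$R_A)
    stop("anatomy_params: constraint R_Di > R_A violated")
  if (p$R_Do <= p$R_Di)
    stop("anatomy_params: constraint R_Do > R_Di violated")
  if (p$R_OM <= p$R_Eq)
    stop("anatomy_params: constraint R_OM > R_Eq violated ",
         "(globe does not fit in the orbit margin)")
  if (p$L_O <= 2 * p$R_P)
    stop("anatomy_params: constraint L_O > 2 * R_P violated ",
         "(globe does not fit in the orbit)")
  if (p$L_O - (p$R_P + p$h_P) <= 1.0)
    stop("anatomy_params: posterior globe leaves no room for the optic nerve ",
         "(L_O must exceed R_P + h_P + 1 mm)")
  if (p$R_A >= 0.5 * p$R_Eq)
    stop("anatomy_params: constraint R_A << R_Eq violated (canal too wide)")
  invisible(TRUE)
}

#' @exportS3Method base::print
print.anatomy_params <- function(x, ...) {
  cat("<anatomy_params> (mm; sas_band um)\n")
  print(unlist(x))
  invisible(x)
}

#' Named preset cases for the baseline study and sensitivity analyses
#'
#' Returns the baseline parameter bundle (anatomy + tissue registry + load
#' case) with exactly one named perturbation applied.
#'
#' Available presets: `baseline`; `plus10_RP`, `plus10_REq`, `plus10_LO`,
#' `plus10_ROM`, `plus10_LOM` (+10% on one anatomical dimension);
#' `soft_sclera_<E>` with `<E>` the scleral modulus in MPa (e.g.
#' `soft_sclera_0.25`); `icp_<value>` with `<value>` in cmH2O (applied in the
#' swollen state); `active_eom` (muscle multiplier M = 2.25); and
#' `fat_E_<Pa>` / `vitreous_E_<Pa>` for the fluid-modulus null checks.
#'
#' @param name preset identifier.
#' @return list with `params` ([anatomy_params()]), `tissues`
#'   ([tissue_registry()]) and `loads` ([load_case()]).
#' @export
preset_case <- function(name) {
  known <- c("baseline", "plus10_RP", "plus10_REq", "plus10_LO", "plus10_ROM",
             "plus10_LOM", "soft_sclera_<E>", "icp_<value>", "active_eom",
             "fat_E_<Pa>", "vitreous_E_<Pa>")
  out <- list(params = anatomy_params(), tissues = tissue_registry(),
              loads = load_case())
  if (name == "baseline") {
  } else if (name == "plus10_RP") {
    out$params$R_P <- out$params$R_P * 1.1
  } else if (name == "plus10_REq") {
    out$params$R_Eq <- out$params$R_Eq * 1.1
  } else if (name == "plus10_LO") {
    out$params$L_O <- out$params$L_O * 1.1
  } else if (name == "plus10_ROM") {
    out$params$R_OM <- out$params$R_OM * 1.1
  } else if (name == "plus10_LOM") {
    out$params$L_OM <- out$params$L_OM * 1.1
  } else if (grepl("^soft_sclera_", name)) {
    E <- suppressWarnings(as.numeric(sub("^soft_sclera_", "", name)))
    if (!is.finite(E) || E <= 0)
      stop("preset_case: bad scleral modulus in '", name, "'")
    out$tissues <- tissue_registry(E_sclera = E * 1e6)
  } else if (grepl("^icp_", name)) {
    v <- suppressWarnings(as.numeric(sub("^icp_", "", name)))
    if (!is.finite(v) || v < 0 || v > 40)
      stop("preset_case: bad ICP in '", name, "'")
    out$loads$ICP <- v
  } else if (name == "active_eom") {
    out$loads$M <- 2.25
  } else if (grepl("^fat_E_", name)) {
    E <- suppressWarnings(as.numeric(sub("^fat_E_", "", name)))
    if (!is.finite(E) || E <= 0) stop("preset_case: bad fat modulus in '", name, "'")
    out$tissues <- tissue_registry(E_fat = E)
  } else if (grepl("^vitreous_E_", name)) {
    E <- suppressWarnings(as.numeric(sub("^vitreous_E_", "", name)))
    if (!is.finite(E) || E <= 0)
      stop("preset_case: bad vitreous modulus in '", name, "'")
    out$tissues <- tissue_registry(E_vitreous = E)
  } else {
    stop("preset_case: unknown preset '", name, "'. Known presets: ",
         paste(known, collapse = ", "))
  }
  validate_anatomy(out$params)
  out
}
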