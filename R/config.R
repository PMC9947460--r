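#' Save / load a case bundle as a YAML config
#'
#' A case bundle (anatomy parameters, tissue moduli, load case) round-trips
#' through a structured YAML file.
#'
#' @param case list with `params`, `tissues`, `loads` (see [preset_case()]).
#' @param file path to the YAML file.
#' @return `config_save` returns the path invisibly; `config_load` the case
#'   bundle.
#' @export
config_save <- function(case, file) {
  E <- setNames(as.list(case$tissues$E[!case$tissues$rigid]),
                case$tissues$name[!case$tissues$rigid])
  obj <- list(anatomy = unclass(case$params),
              tissues = E,
              loads = unclass(case$loads))
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname config_save
#' @export
config_load <- function(file) {
  obj <- yaml::read_yaml(file)
  params <- do.call(anatomy_params, obj$anatomy)
  tissues <- tissue_registry(E_sclera = obj$tissues$ocular_coats,
                             E_vitreous = obj$tissues$vitreous,
                             E_fat = obj$tissues$orbital_fat,
                             E_bundle = obj$tissues$axon_bundle,
                             E_dura = obj$tissues$dura)
  ld <- obj$loads
  ld$eps_H_fat <- as.numeric(unlist(ld$eps_H_fat))
  loads <- do.call(load_case, ld)
  list(params = params, tissues = tissues, loads = loads)
}
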