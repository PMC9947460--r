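# Drivers for the baseline table and the three sensitivity studies.
# Every sweep returns a long-format data.frame (one row per case x schedule
# point) with provenance attributes; failed cells are flagged, not dropped.

.case_key <- function(case, loads, density, order) {
  rlang::hash(list(case$params, case$tissues$E, loads, density, order))
}

# run a protocol with an on-disk cache (resumable sweeps)
.cached_protocol <- function(case, loads, density, order, out_dir = NULL, ...) {
  key <- .case_key(case, loads, density, order)
  f <- if (!is.null(out_dir)) file.path(out_dir, paste0("cell-", key, ".csv")) else NULL
  if (!is.null(f) && file.exists(f))
    return(list(biometrics = read_sweep_csv(f), cached = TRUE, key = key))
  pr <- run_protocol(case, loads = loads, density = density, order = order, ...)
  if (!is.null(f)) {
    dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
    write_sweep_csv(pr$biometrics, f)
  }
  list(biometrics = pr$biometrics, result = pr, cached = FALSE, key = key)
}

.sweep_result <- function(rows, spec) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(spec = spec,
                                  package_version = as.character(utils::packageVersion("orbitfem")),
                                  created = format(Sys.time(), "%Y-%m-%d"))
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Baseline fat-swelling table
#'
#' Runs the baseline protocol over the full swelling schedule (hygroscopic
#' strain 0 to 0.070) and returns one biometric row per schedule point.
#'
#' @param case preset name or case bundle (default `"baseline"`).
#' @param density,order meshing controls; the headline table defaults to the
#'   quartic eye.
#' @param out_dir optional output directory (enables resumable caching).
#' @param ... passed to [run_protocol()].
#' @return a `sweep_result` data.frame (14 rows for the default schedule).
#' @export
run_table2 <- function(case = "baseline", density = "coarse", order = 4,
                       out_dir = NULL, ...) {
  if (is.character(case)) case <- preset_case(case)
  r <- .cached_protocol(case, case$loads, density, order, out_dir, ...)
  bio <- r$biometrics
  bio$case <- "baseline"
  .sweep_result(list(bio), list(kind = "table2", density = density, order = order))
}

#' ICP x fat-swelling factorial sweep
#'
#' @param icp_values ICP grid (cmH2O, within `[0, 40]`).
#' @param eps_values fat hygroscopic strain grid (non-negative, sorted).
#' @inheritParams run_table2
#' @return a `sweep_result` with one row per (ICP, eps) cell and an
#'   `effect_summary` attribute (range over ICP vs range over swelling for
#'   each biometric).
#' @export
run_icp_grid <- function(icp_values = c(0, 20),
                         eps_values = c(0, 0.07),
                         case = "baseline", density = "coarse", order = 2,
                         out_dir = NULL, ...) {
  if (length(icp_values) == 0 || length(eps_values) == 0)
    stop("run_icp_grid: grids must be non-empty")
  if (is.character(case)) case <- preset_case(case)
  eps_values <- sort(eps_values)
  rows <- list()
  for (icp in icp_values) {
    loads <- case$loads
    loads$ICP <- icp
    loads$eps_H_fat <- eps_values
    cell <- tryCatch(.cached_protocol(case, loads, density, order, out_dir, ...),
                     error = function(e) e)
    if (inherits(cell, "error")) {
      rows[[length(rows) + 1]] <- data.frame(eps_H_fat = eps_values,
                                             ICP_cmH2O = icp, failed = TRUE,
                                             message = conditionMessage(cell))
    } else {
      b <- cell$biometrics
      b$failed <- FALSE
      rows[[length(rows) + 1]] <- b
    }
  }
  out <- .sweep_result(rows, list(kind = "icp_grid", icp = icp_values,
                                  eps = eps_values, density = density))
  ok <- !out$failed
  if (any(ok)) {
    vars <- c("proptosis_mm", "dAL_um", "darc_um", "dROC_mm")
    eff <- sapply(vars, function(v) {
      # range over ICP at max swelling vs range over swelling at terrestrial ICP
      at_max_eps <- out[ok & out$eps_H_fat == max(eps_values), v]
      at_fixed_icp <- out[ok & out$ICP_cmH2O == out$ICP_cmH2O[which.max(ok)], v]
      c(range_ICP = diff(range(at_max_eps)),
        range_swelling = diff(range(at_fixed_icp)))
    })
    attr(out, "effect_summary") <- t(eff)
  }
  out
}

#' Anatomical sensitivity study (+10% perturbations)
#'
#' Runs the baseline and the five +10% anatomical perturbations (polar radius,
#' equatorial radius, orbit depth, orbit margin radius, orbit margin length)
#' at a fixed fat-swelling level and reports biometric deltas against the
#' baseline.
#'
#' @param eps_level fat hygroscopic strain at which cases are compared
#'   (default 0.07, the schedule maximum).
#' @inheritParams run_table2
#' @return a `sweep_result` with one row per case, plus delta columns.
#' @export
run_anatomy_sensitivity <- function(eps_level = 0.07, density = "coarse",
                                    order = 2, out_dir = NULL, ...) {
  presets <- c("baseline", "plus10_RP", "plus10_REq", "plus10_LO",
               "plus10_ROM", "plus10_LOM")
  sched <- seq(0, eps_level, length.out = 6)
  rows <- list()
  for (nm in presets) {
    case <- preset_case(nm)
    loads <- case$loads
    loads$eps_H_fat <- sched
    cell <- tryCatch(.cached_protocol(case, loads, density, order, out_dir, ...),
                     error = function(e) e)
    if (inherits(cell, "error")) {
      rows[[nm]] <- data.frame(case = nm, failed = TRUE,
                               message = conditionMessage(cell))
    } else {
      b <- cell$biometrics[nrow(cell$biometrics), , drop = FALSE]
      b$case <- nm
      b$failed <- FALSE
      rows[[nm]] <- b
    }
  }
  out <- .sweep_result(rows, list(kind = "anatomy", eps_level = eps_level,
                                  density = density))
  if (!any(out$failed) && "baseline" %in% out$case) {
    base <- out[out$case == "baseline", ]
    for (v in c("proptosis_mm", "dAL_um", "darc_um", "dROC_mm"))
      out[[paste0("delta_", v)]] <- out[[v]] - base[[v]]
  }
  out
}

#' Tissue-stiffness sweeps
#'
#' Varies the scleral modulus over the requested values and (optionally) runs
#' the fat and vitreous modulus null-effect checks, at a fixed swelling level.
#'
#' @param E_sclera_MPa scleral moduli to test (MPa).
#' @param fluid_nulls also run fat 0.7/1.5 kPa and vitreous 6.5/25 Pa.
#' @inheritParams run_anatomy_sensitivity
#' @return a `sweep_result`, one row per case.
#' @export
run_stiffness_sweep <- function(E_sclera_MPa = c(0.25, 1.5, 5),
                                fluid_nulls = FALSE, eps_level = 0.07,
                                density = "coarse", order = 2, out_dir = NULL,
                                ...) {
  stopifnot(all(E_sclera_MPa > 0))
  cases <- lapply(E_sclera_MPa, function(E)
    list(name = sprintf("sclera_%g_MPa", E),
         case = preset_case(sprintf("soft_sclera_%g", E))))
  if (fluid_nulls) {
    cases <- c(cases,
               lapply(c(700, 1500), function(E)
                 list(name = sprintf("fat_%g_Pa", E),
                      case = preset_case(sprintf("fat_E_%g", E)))),
               lapply(c(6.5, 25), function(E)
                 list(name = sprintf("vitreous_%g_Pa", E),
                      case = preset_case(sprintf("vitreous_E_%g", E)))))
  }
  sched <- seq(0, eps_level, length.out = 6)
  rows <- list()
  for (cs in cases) {
    loads <- cs$case$loads
    loads$eps_H_fat <- sched
    cell <- tryCatch(.cached_protocol(cs$case, loads, density, order, out_dir, ...),
                     error = function(e) e)
    if (inherits(cell, "error")) {
      rows[[cs$name]] <- data.frame(case = cs$name, failed = TRUE,
                                    message = conditionMessage(cell))
    } else {
      b <- cell$biometrics[nrow(cell$biometrics), , drop = FALSE]
      b$case <- cs$name
      b$failed <- FALSE
      rows[[cs$name]] <- b
    }
  }
  .sweep_result(rows, list(kind = "stiffness", E_sclera_MPa = E_sclera_MPa,
                           eps_level = eps_level, density = density))
}

#' Write / read a sweep table as CSV (lossless round trip)
#' @param x a data.frame.
#' @param file path.
#' @return the file path (write) or the data.frame (read).
#' @export
write_sweep_csv <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
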