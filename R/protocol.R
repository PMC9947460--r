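# The staged loading protocol:
#   A: inverse identification of the zero-stress eye (radii + vitreous swelling)
#   B: residually stressed, pressurised eye (vitreous swelling + ICP band)
#   C: terrestrial state - eye seated in the orbit, muscle tension ramped in
#   D: microgravity state - orbital fat swelling (and ICP) incremented
# All reported biometric changes are D relative to C.

# measure achieved inner semi-axes and IOP on an eye mesh at displacement u
.measure_eye <- function(mesh, tissues, u, eps_v) {
  pts <- sample_edges(mesh, mesh$chain_edges$inner_sclera, u, n_per_edge = 12)
  a_ach <- max(pts[, 1])
  ap <- mesh$chains$inner_sclera[1] # inner anterior pole (axis)
  dc <- mesh$sets$disc_center
  b_ach <- ((mesh$nodes[ap, 2] + u[2 * ap]) - (mesh$nodes[dc, 2] + u[2 * dc])) / 2
  ef <- element_fields(mesh, tissues, u, eps_v = eps_v)
  vit <- mesh$region == 2L
  IOP_Pa <- -sum(ef[vit, "hydro"] * ef[vit, "vol"]) / sum(ef[vit, "vol"])
  list(a = a_ach, b = b_ach, IOP = pressure_convert(IOP_Pa, "Pa", "mmHg"))
}

#' Identify the zero-stress configuration of the eye (Model A)
#'
#' Finds the zero-stress polar and equatorial inner radii and the vitreous
#' hygroscopic strain such that loading the zero-stress eye with vitreous
#' swelling (and the terrestrial ICP band traction) reproduces the target
#' geometry and target IOP. The search is a cyclic coordinate update: radius
#' mismatches feed back additively (the inflation displacement depends only
#' weakly on the zero-stress radii) and the vitreous strain is updated by a
#' secant step on the achieved IOP.
#'
#' @param params target [anatomy_params()].
#' @param tissues a [tissue_registry()].
#' @param loads a [load_case()]; supplies the target IOP, terrestrial ICP and
#'   the IOP mode.
#' @param density,order meshing controls (see [mesh_eye()]).
#' @param tol_r radius tolerance (mm), default 2e-3 (the contract is 10 um).
#' @param tol_p IOP tolerance (mmHg), default 0.02 (the contract is 0.1).
#' @param maxit maximum coordinate iterations.
#' @return a `zero_stress_result`: zero-stress radii, vitreous strain, achieved
#'   IOP, geometric mismatch (um), realized vitreous gap `g_v` (um), plus the
#'   final eye mesh and Model-B state used to seed the orbital stages.
#' @export
find_zero_stress <- function(params, tissues = tissue_registry(),
                             loads = load_case(), density = "coarse",
                             order = 2, tol_r = 2e-3, tol_p = 0.02,
                             maxit = 30) {
  a_t <- params$R_Eq; b_t <- params$R_P
  direct <- loads$iop_mode == "direct"
  p_Pa <- pressure_convert(loads$IOP_target, "mmHg", "Pa")
  h_avg <- (params$h_Eq + params$h_P) / 2
  E_s <- tissues$E[tissues$name == "ocular_coats"]
  d0 <- p_Pa * a_t^2 * 0.5 / (2 * E_s * h_avg) # thin-shell inflation estimate
  a0 <- a_t - d0; b0 <- b_t - d0
  ev <- if (direct) 0 else max(d0 / a_t, 1e-6)
  ev_prev <- NA; IOP_prev <- NA
  history <- NULL
  best <- NULL
  warm <- NULL
  eval_case <- function(a0, b0, ev) {
    pp <- params
    pp$R_Eq <- a0; pp$R_P <- b0
    geom0 <- build_anatomy(pp, insertion_theta = loads$insertion_theta)
    mesh <- mesh_eye(geom0, density, order)
    ctx <- solve_context(mesh, tissues, loads, stage = "eye",
                         direct_iop = direct, pin = "anterior_pole")
    target <- list(eps_v = ev, eps_fat = 0, ICP = loads$ICP_terrestrial,
                   M = 0, IOP = if (direct) loads$IOP_target else 0)
    st <- NULL
    if (!is.null(warm)) {
      # candidate meshes share topology: the previous converged state is an
      # excellent initial guess for a single direct solve
      res <- newton_solve(ctx, warm$u, target, p0 = warm$p)
      if (res$converged)
        st <- list(u = res$u, p = res$p, resid = res$resid)
    }
    if (is.null(st)) {
      sch <- data.frame(eps_v = ev * c(1 / 3, 2 / 3, 1),
                        eps_fat = 0,
                        ICP = loads$ICP_terrestrial * c(1 / 3, 2 / 3, 1),
                        M = 0,
                        IOP = if (direct) loads$IOP_target * c(1 / 3, 2 / 3, 1) else 0)
      states <- step_continuation(ctx, sch)
      st <- states[[length(states)]]
    }
    warm <<- list(u = st$u, p = st$p)
    meas <- .measure_eye(mesh, tissues, st$u, if (direct) 0 else ev)
    if (direct) meas$IOP <- loads$IOP_target
    list(mesh = mesh, geom0 = geom0, state = st, meas = meas)
  }
  for (it in seq_len(maxit)) {
    ec <- eval_case(a0, b0, ev)
    mis_a <- ec$meas$a - a_t
    mis_b <- ec$meas$b - b_t
    mis_p <- ec$meas$IOP - loads$IOP_target
    history <- rbind(history, data.frame(it = it, a0 = a0, b0 = b0, eps_v = ev,
                                         mis_a = mis_a, mis_b = mis_b,
                                         mis_p = mis_p))
    score <- max(abs(mis_a), abs(mis_b)) + abs(mis_p) * 1e-2
    if (is.null(best) || score < best$score)
      best <- list(score = score, a0 = a0, b0 = b0, ev = ev, ec = ec,
                   mis = c(mis_a, mis_b, mis_p))
    if (abs(mis_a) < tol_r && abs(mis_b) < tol_r &&
        (direct || abs(mis_p) < tol_p)) {
      out <- list(R_Eq0 = a0, R_P0 = b0, eps_v = ev,
                  IOP_achieved = ec$meas$IOP,
                  mismatch_um = c(equatorial = mis_a, polar = mis_b) * 1000,
                  g_v_um = c(equatorial = (a_t - a0) * 1000,
                             polar = (b_t - b0) * 1000),
                  iterations = it, converged = TRUE, history = history,
                  mesh = ec$mesh, geom0 = ec$geom0, state_B = ec$state)
      class(out) <- "zero_stress_result"
      return(out)
    }
    # cyclic coordinate updates
    a0 <- a0 - mis_a
    b0 <- b0 - mis_b
    if (!direct) {
      if (!is.na(ev_prev) && abs(ec$meas$IOP - IOP_prev) > 1e-9) {
        step <- mis_p * (ev - ev_prev) / (ec$meas$IOP - IOP_prev)
        ev_new <- ev - step
      } else {
        ev_new <- ev * loads$IOP_target / max(ec$meas$IOP, 1e-6)
      }
      ev_prev <- ev; IOP_prev <- ec$meas$IOP
      ev <- min(max(ev_new, 1e-8), 0.2)
    }
  }
  stop("find_zero_stress: coordinate search stagnated before tolerance; ",
       sprintf("best mismatch (um): equatorial %.1f, polar %.1f; IOP %.3f mmHg",
               best$mis[1] * 1000, best$mis[2] * 1000, best$mis[3]))
}

#' @exportS3Method base::print
print.zero_stress_result <- function(x, ...) {
  cat("<zero_stress_result>\n")
  cat(sprintf("  zero-stress radii : R_Eq0 = %.4f, R_P0 = %.4f mm\n",
              x$R_Eq0, x$R_P0))
  cat(sprintf("  vitreous strain   : %.5f (J_H = %.4f)\n",
              x$eps_v, (1 + x$eps_v)^3))
  cat(sprintf("  achieved IOP      : %.3f mmHg\n", x$IOP_achieved))
  cat(sprintf("  mismatch          : %.2f / %.2f um\n",
              x$mismatch_um[1], x$mismatch_um[2]))
  cat(sprintf("  vitreous gap g_v  : %.0f-%.0f um (%d iterations)\n",
              min(x$g_v_um), max(x$g_v_um), x$iterations))
  invisible(x)
}

#' Run the full four-stage loading protocol
#'
#' Identifies the zero-stress eye, loads it to the residually stressed state
#' (Model B), seats it in the orbit and ramps the extraocular-muscle tension
#' (Model C), then increments orbital fat swelling and ICP along the load-case
#' schedule (Model D). Biometrics are reported for every Model-D state
#' relative to Model C.
#'
#' @param case preset name (see [preset_case()]) or a list with `params`,
#'   `tissues`, `loads`.
#' @param loads optional [load_case()] overriding the case's load case.
#' @param density,order meshing controls; `order` is the eye's element order
#'   (the bending-dominated shell response needs quartic elements).
#' @param eye_density optional separate density for the eye mesh; with the
#'   quartic default a coarser grid (target edge ~1.6 mm) resolves the shell.
#' @param fat_order element order of the fat mesh (quadratic suffices: its
#'   response is volumetric/contact-driven, and large sliding is more robust
#'   at moderate order).
#' @param kp_contact contact penalty stiffness (Pa/mm).
#' @param contact_mode `"frictionless"` (default) or `"tied"` (diagnostic).
#' @param n_eom_steps increments of the muscle ramp to Model C.
#' @param zero_stress optional precomputed [find_zero_stress()] result
#'   (must match case/density/order).
#' @return a `protocol_result` with elements `zero_stress`, `mesh`, `B`, `C`,
#'   `D` (list of solution states), `biometrics` (one row per Model-D state)
#'   and `work` (external work / strain energy log).
#' @export
run_protocol <- function(case = "baseline", loads = NULL, density = "coarse",
                         order = 4, fat_order = 2, eye_density = NULL,
                         kp_contact = 1e7,
                         contact_mode = "frictionless", n_eom_steps = 10,
                         zero_stress = NULL) {
  if (is.character(case)) case <- preset_case(case)
  params <- case$params
  tissues <- case$tissues
  if (is.null(loads)) loads <- case$loads
  t0 <- proc.time()[["elapsed"]]
  if (is.null(eye_density))
    eye_density <- if (order >= 4) 1.6 else density
  zs <- zero_stress
  if (is.null(zs))
    zs <- find_zero_stress(params, tissues, loads, eye_density, order)
  direct <- loads$iop_mode == "direct"
  geomT <- build_anatomy(params, insertion_theta = loads$insertion_theta)
  # build the fat against the deformed Model-B eye surface so the two bodies
  # are exactly in contact at rest (the inflated zero-stress eye is not a
  # perfect ellipse away from the equator and pole)
  inner <- .fat_inner_from_state(zs$mesh, zs$state_B$u, params$L_O)
  fat <- mesh_fat(geomT, density, fat_order, inner = inner)
  mesh <- combine_meshes(zs$mesh, fat)
  parsB <- list(eps_v = zs$eps_v, eps_fat = 0, ICP = loads$ICP_terrestrial,
                M = 0, IOP = if (direct) loads$IOP_target else 0)
  u0 <- numeric(2 * nrow(mesh$nodes))
  u0[seq_along(zs$state_B$u)] <- zs$state_B$u # eye nodes come first
  # Model B within the orbit (apex still pinned, muscle off, fat unswollen)
  ctxB <- solve_context(mesh, tissues, loads, stage = "orbit",
                        direct_iop = direct, kp_contact = kp_contact,
                        contact_mode = contact_mode, pin = "anterior_pole")
  p0 <- numeric(ctxB$np)
  p0[seq_along(zs$state_B$p)] <- zs$state_B$p # eye elements come first
  stB <- step_continuation(ctxB, as.data.frame(parsB), u0 = u0, p0 = p0,
                           pars0 = parsB)[[1]]
  # Model C: release the apex pin, ramp the muscle multiplier
  ctx <- solve_context(mesh, tissues, loads, stage = "orbit",
                       direct_iop = direct, kp_contact = kp_contact,
                       contact_mode = contact_mode)
  Mseq <- if (loads$M > 0) seq(0, loads$M, length.out = n_eom_steps + 1)[-1] else 0
  schC <- data.frame(eps_v = zs$eps_v, eps_fat = 0,
                     ICP = loads$ICP_terrestrial, M = Mseq,
                     IOP = if (direct) loads$IOP_target else 0)
  statesC <- step_continuation(ctx, schC, u0 = stB$u, p0 = stB$p,
                               pars0 = parsB)
  stC <- statesC[[length(statesC)]]
  # Model D: fat swelling (and ICP) incremented along the schedule
  eps_sched <- loads$eps_H_fat
  if (length(eps_sched) == 0) eps_sched <- 0
  fr <- if (max(eps_sched) > 0) eps_sched / max(eps_sched) else rep(1, length(eps_sched))
  schD <- data.frame(eps_v = zs$eps_v, eps_fat = eps_sched,
                     ICP = loads$ICP_terrestrial +
                       (loads$ICP - loads$ICP_terrestrial) * fr,
                     M = loads$M,
                     IOP = if (direct) loads$IOP_target else 0)
  statesD <- step_continuation(ctx, schD, u0 = stC$u, p0 = stC$p,
                               pars0 = as.list(schC[nrow(schC), ]))
  bio <- do.call(rbind, lapply(seq_along(statesD), function(k) {
    st <- statesD[[k]]
    biometric_row(mesh, st$u, stC$u, eps_fat = schD$eps_fat[k],
                  pars = st$pars, state = st)
  }))
  rownames(bio) <- NULL
  # external work vs strain energy along C and D (energy-consistency log)
  work <- .work_log(c(list(stB), statesC, statesD))
  out <- list(zero_stress = zs, mesh = mesh, B = stB, C = stC, D = statesD,
              statesC = statesC, biometrics = bio, loads = loads,
              params = params, tissues = tissues,
              density = density, order = order,
              elapsed_s = proc.time()[["elapsed"]] - t0)
  class(out) <- "protocol_result"
  out
}

.work_log <- function(states) {
  W_ext <- 0
  rows <- lapply(seq_along(states), function(k) {
    st <- states[[k]]
    if (k > 1) {
      prev <- states[[k - 1]]
      du <- st$u - prev$u
      W_ext <<- W_ext + 0.5 * sum((st$Fext + prev$Fext) * du)
    }
    data.frame(step = k, W_strain = st$W, E_contact = st$E_contact,
               W_ext_cum = W_ext)
  })
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  print(x$zero_stress)
  cat(sprintf("  mesh: %d nodes (order %d), contact slaves %d\n",
              nrow(x$mesh$nodes), x$order, length(x$mesh$contact$slave)))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  cat("  biometrics (Model D relative to Model C):\n")
  print(x$biometrics[, c("eps_H_fat", "J_H", "proptosis_mm", "dAL_um",
                         "darc_um", "dROC_mm")], digits = 4)
  invisible(x)
}

# deformed fat inner boundary (dura foot -> globe -> rim-plane crossing) from
# an eye mesh state
.fat_inner_from_state <- function(eyemesh, u, L_O, n_per_edge = 8,
                                  standoff = 0) {
  ed <- eyemesh$chain_edges$master
  pts <- sample_edges(eyemesh, ed, u, n_per_edge = n_per_edge)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg))
  L_dura <- cum[eyemesh$sets$n_dura_edges * n_per_edge]
  # truncate at the rim-plane crossing (single crossing, past the equator)
  ix <- which(pts[, 2] > L_O)
  if (length(ix) == 0)
    stop(".fat_inner_from_state: deformed globe does not reach the rim plane")
  k <- ix[1]
  f <- (L_O - pts[k - 1, 2]) / (pts[k, 2] - pts[k - 1, 2])
  xc <- pts[k - 1, ] + f * (pts[k, ] - pts[k - 1, ])
  pts <- rbind(pts[seq_len(k - 1), , drop = FALSE], xc)
  keep <- c(TRUE, sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  # offset by the contact-regularisation standoff so the built state carries
  # no spurious interface pressure (zero pressure at gap = standoff)
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ], pts[3:n, ] - pts[1:(n - 2), ],
              pts[n, ] - pts[n - 1, ])
  nrm <- cbind(tg[, 2], -tg[, 1]) / sqrt(rowSums(tg^2))
  pts <- pts + standoff * nrm
  list(pts = pts, L_dura = L_dura)
}
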