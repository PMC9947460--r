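# Nonlinear equilibrium solves: total-Lagrangian assembly through the compiled
# kernels, Newton iteration with backtracking line search, and load-stepping
# continuation with automatic bisection.

.basis_cache <- new.env(parent = emptyenv())

basis_tables <- function(order) {
  key <- as.character(order)
  tb <- .basis_cache[[key]]
  if (is.null(tb)) {
    dg <- quad_degrees(order)
    tb <- list(dev = tri_basis_table(order, dg[["dev"]]),
               vol = tri_basis_table(order, dg[["vol"]]),
               vol1 = tri_basis_table(order, 1),
               edge = edge_basis_table(order),
               mid = tri_basis_table(order, dg[["dev"]]),
               vedge_idx = tri_edge_indices(order),
               vedge = tri_volume_edge_basis(order))
    .basis_cache[[key]] <- tb
  }
  tb
}

# per-element material columns (mu, kappa, J_H); vitreous and fat carry their
# current hygroscopic volume ratios
material_rows <- function(mesh, tissues, J_H_vitreous = 1, J_H_fat = 1) {
  idx <- match(mesh$region_names[mesh$region], tissues$name)
  mu <- tissues$mu[idx]
  kappa <- tissues$kappa[idx]
  JH <- rep(1, length(idx))
  JH[mesh$region == 2L] <- J_H_vitreous
  JH[mesh$region == 3L] <- J_H_fat
  cbind(mu = mu, kappa = kappa, JH = JH)
}

# solve context: everything fixed during one Newton solve
solve_context <- function(mesh, tissues, loads,
                          stage = c("eye", "orbit"),
                          direct_iop = FALSE, kp_contact = 1e7,
                          contact_mode = c("frictionless", "tied"),
                          pin = c("none", "anterior_pole", "apex")) {
  stage <- match.arg(stage)
  contact_mode <- match.arg(contact_mode)
  ndof <- 2L * nrow(mesh$nodes)
  blocks <- list()
  used_nodes <- integer(0)
  for (nm in names(mesh$blocks)) {
    b <- mesh$blocks[[nm]]
    active <- if (direct_iop) which(b$region != 2L) else seq_len(ncol(b$elems))
    el <- b$elems[, active, drop = FALSE]
    nen <- nrow(el)
    edof <- matrix(0L, 2L * nen, ncol(el))
    edof[seq(1, 2 * nen, 2), ] <- 2L * el - 1L
    edof[seq(2, 2 * nen, 2), ] <- 2L * el
    blocks[[nm]] <- list(el = el, region = b$region[active],
                         order = b$order, nE = ncol(el),
                         fluid = which(b$region[active] %in% c(2L, 3L)),
                         edof = edof, tab = basis_tables(b$order))
    used_nodes <- c(used_nodes, unique(as.vector(el)))
  }
  fixed <- 2L * mesh$sets$axis - 1L # u_r on the axis
  if (direct_iop) {
    orphan <- setdiff(seq_len(nrow(mesh$nodes)), unique(used_nodes))
    fixed <- c(fixed, 2L * orphan - 1L, 2L * orphan)
  }
  if (!is.null(mesh$sets$wall))
    fixed <- c(fixed, 2L * mesh$sets$wall - 1L, 2L * mesh$sets$wall)
  pin <- match.arg(pin)
  if (pin == "apex") fixed <- c(fixed, 2L * mesh$sets$apex)
  if (pin == "anterior_pole") fixed <- c(fixed, 2L * mesh$sets$anterior_pole)
  np <- sum(vapply(blocks, function(b) b$nE, 1))
  ctx <- list(mesh = mesh, tissues = tissues, loads = loads, stage = stage,
              direct_iop = direct_iop, kp = kp_contact,
              blocks = blocks, np = np,
              fixed = sort(unique(fixed)),
              g0 = 0.02, edgeC = edge_basis_coeffs(mesh$order),
              tab = basis_tables(mesh$order), ndof = ndof,
              sub_phi = edge_basis_eval(mesh$order, seq(0, 1, length.out = 6))$phi)
  if (stage == "orbit") {
    # muscle insertion: a ring band ~2 mm wide (tendon footprint) around the
    # insertion station, with consistent (arc-length) weights; the law is
    # evaluated at the work-conjugate band-averaged displacement
    th <- mesh$sets$outer_theta
    thi <- th[match(mesh$sets$insertion, mesh$chains$outer_sclera)]
    halfw <- 0 # point insertion (ring); set > 0 for a distributed tendon band
    bandn <- which(abs(th - thi) <= halfw)
    ids <- mesh$chains$outer_sclera[bandn]
    wts <- rep(1, length(ids))
    if (length(ids) > 2) {
      arc <- c(0, cumsum(sqrt(diff(mesh$nodes[ids, 1])^2 +
                                diff(mesh$nodes[ids, 2])^2)))
      wts <- c(diff(arc) / 2, 0) + c(0, diff(arc) / 2)
    }
    ctx$ins_nodes <- ids
    ctx$ins_w <- wts / sum(wts)
    ns <- length(mesh$contact$slave)
    smode <- integer(ns)
    if (contact_mode == "tied") smode[] <- 1L
    # material pairing from the reference configuration
    cc0 <- asm_contact_cpp(mesh$nodes, numeric(ctx$ndof), mesh$contact$slave,
                           mesh$contact$slave_w, mesh$contact$master_edges,
                           ctx$sub_phi, ctx$edgeC, kp_contact, ctx$g0,
                           integer(ns), integer(ns), numeric(ns))
    ctx$smode <- smode
    ctx$tied_edge <- cc0$seg
    ctx$tied_s <- cc0$t
  }
  ctx
}

# assemble residual, tangent and diagnostics at displacement u and element
# pressures p under stage parameters pars = list(eps_v, eps_fat, ICP, M, IOP).
# Incompressibility by a mixed displacement-pressure (perturbed Lagrangian)
# formulation with element-wise constant pressure, condensed exactly into the
# displacement system; `mv` carries what the pressure update needs.
fe_assemble <- function(ctx, u, pars, p) {
  mesh <- ctx$mesh
  R <- numeric(ctx$ndof)
  Radd <- numeric(ctx$ndof)
  ti <- list(); tj <- list(); tx <- list()
  Wtot <- 0
  mv <- list()
  off <- 0L
  for (nm in names(ctx$blocks)) {
    b <- ctx$blocks[[nm]]
    mat <- material_rows_block(b$region, ctx$tissues,
                               (1 + pars$eps_v)^3, (1 + pars$eps_fat)^3)
    pb <- p[off + seq_len(b$nE)]
    fl <- b$fluid
    solid <- if (length(fl)) seq_len(b$nE)[-fl] else seq_len(b$nE)
    va <- asm_volume_cpp(mesh$nodes, b$el,
                         cbind(mat[, 1], 0, mat[, 3]),
                         cbind(0, 0, mat[, 3]),
                         u, b$tab$dev, b$tab$vol1)
    if (!va$ok) return(list(ok = FALSE, bad_elem = va$bad_elem))
    mq <- asm_mixedq_cpp(mesh$nodes, b$el[, solid, drop = FALSE],
                         cbind(mat[solid, 2], mat[solid, 3]), u, pb[solid],
                         b$tab$dev)
    if (!mq$ok) return(list(ok = FALSE, bad_elem = mq$bad_elem))
    vm <- asm_mixedvol_cpp(mesh$nodes, b$el[, fl, drop = FALSE],
                           cbind(mat[fl, 2], mat[fl, 3]),
                           u, pb[fl], b$tab$vedge_idx, b$tab$vedge)
    if (!vm$ok) return(list(ok = FALSE, bad_elem = vm$bad_elem))
    R <- R + va$R + mq$Ru + vm$Ru
    kap <- mat[, 2]
    JHe <- mat[, 3]
    Rp <- numeric(b$nE); Rp[solid] <- mq$Rp; Rp[fl] <- vm$Rp
    V0 <- numeric(b$nE); V0[solid] <- mq$V0; V0[fl] <- vm$V0
    Jbar <- numeric(b$nE); Jbar[solid] <- mq$Jbar; Jbar[fl] <- vm$Jbar
    bmat <- matrix(0, nrow(b$edof), b$nE)
    bmat[, solid] <- mq$b
    bmat[, fl] <- vm$b
    # condensation of the pressure residual into the displacement system
    coef <- kap * Rp / (V0 * JHe)
    val <- as.vector(bmat) * rep(coef, each = nrow(bmat))
    agg <- rowsum(val, group = as.vector(b$edof), reorder = TRUE)
    Radd[as.integer(rownames(agg))] <- Radd[as.integer(rownames(agg))] + agg[, 1]
    mv[[nm]] <- list(Rp = Rp, b = bmat, V0 = V0, Jbar = Jbar,
                     kap = kap, JHe = JHe, off = off, edof = b$edof)
    ti <- c(ti, list(va$i, mq$i, vm$i))
    tj <- c(tj, list(va$j, mq$j, vm$j))
    tx <- c(tx, list(va$x, mq$x, vm$x))
    Wtot <- Wtot + va$W + mq$W + vm$W
    off <- off + b$nE
  }
  Fext <- numeric(ctx$ndof)
  info <- list(W = Wtot, F_ICP = 0, F_fat = 0, F_EOM = 0, F_ON = 0,
               E_contact = 0, gaps = NULL, pn = NULL)
  # ICP band traction (follower)
  if (pars$ICP > 0) {
    band <- if (identical(ctx$loads$icp_band, "outer_annulus"))
      mesh$chain_edges$sas_band_outer else mesh$chain_edges$sas_band
    pr <- asm_pressure_cpp(mesh$nodes, band, u,
                           pressure_convert(pars$ICP, "cmH2O", "Pa"),
                           ctx$tab$edge, ctx$ndof)
    Fext <- Fext + pr$F
    info$F_ICP <- pr$fz / 1000
  }
  # direct IOP mode: follower pressure on the inner shell surface + disc
  if (ctx$direct_iop && pars$IOP > 0) {
    pr <- asm_pressure_cpp(mesh$nodes, mesh$chain_edges$iop_surface, u,
                           pressure_convert(pars$IOP, "mmHg", "Pa"),
                           ctx$tab$edge, ctx$ndof)
    Fext <- Fext + pr$F
  }
  if (ctx$stage == "orbit") {
    # sliding contact between sclera/dura and fat
    cc <- asm_contact_cpp(mesh$nodes, u, mesh$contact$slave,
                          mesh$contact$slave_w, mesh$contact$master_edges,
                          ctx$sub_phi, ctx$edgeC, ctx$kp, ctx$g0,
                          ctx$smode, ctx$tied_edge, ctx$tied_s)
    Fext <- Fext + cc$F
    ti <- c(ti, list(cc$i)); tj <- c(tj, list(cc$j)); tx <- c(tx, list(cc$x))
    info$F_fat <- cc$fz_master / 1000
    info$E_contact <- cc$energy
    info$gaps <- cc$gap
    info$pn <- cc$pn
    # extraocular-muscle band load (posterior pull, magnitude from the law
    # at the band-averaged anterior displacement)
    if (pars$M > 0) {
      nid <- ctx$ins_nodes
      om <- ctx$ins_w
      wz <- sum(om * u[2 * nid])
      Fm <- eom_force(wz, pars$M)
      Fext[2 * nid] <- Fext[2 * nid] - 1000 * Fm * om
      kb <- 1000 * eom_force_dw(wz, pars$M) * outer(om, om)
      ti <- c(ti, list(rep(2L * nid, each = length(nid))))
      tj <- c(tj, list(rep(2L * nid, times = length(nid))))
      tx <- c(tx, list(as.vector(kb)))
      info$F_EOM <- Fm
      info$w_insertion <- wz
    }
    # optic-nerve slack spring at the nerve apex
    ka <- ctx$loads$on_spring_stiffness
    sl <- ctx$loads$on_slack_threshold
    aid <- mesh$sets$apex
    exc <- u[2 * aid] - sl
    if (exc > 0) {
      Fext[2 * aid] <- Fext[2 * aid] - 1000 * ka * exc
      ti <- c(ti, list(2L * aid)); tj <- c(tj, list(2L * aid))
      tx <- c(tx, list(1000 * ka))
      info$F_ON <- ka * exc
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ctx$ndof, ctx$ndof))
  list(ok = TRUE, R = R - Fext, Radd = Radd, K = K, Fext = Fext, info = info,
       mv = mv)
}

# exact per-element pressure increment after a displacement increment
pressure_update <- function(ctx, mv, du) {
  dp <- numeric(ctx$np)
  for (blk in mv) {
    bTdu <- colSums(matrix(du[blk$edof], nrow(blk$b), ncol(blk$b)) * blk$b)
    dp[blk$off + seq_along(blk$Rp)] <-
      (blk$kap / blk$V0) * (blk$Rp + bTdu / blk$JHe)
  }
  dp
}

material_rows_block <- function(region, tissues, J_H_vitreous = 1, J_H_fat = 1) {
  idx <- match(REGION_NAMES[region], tissues$name)
  mu <- tissues$mu[idx]
  kappa <- tissues$kappa[idx]
  JH <- rep(1, length(idx))
  JH[region == 2L] <- J_H_vitreous
  JH[region == 3L] <- J_H_fat
  cbind(mu = mu, kappa = kappa, JH = JH)
}

#' Solve the nonlinear equilibrium at fixed load parameters
#'
#' Newton iteration with backtracking line search on the assembled residual.
#' Convergence: residual 2-norm below `rtol` times the external-force scale
#' (floored at `atol` uN).
#'
#' @param ctx solve context (internal; built by the protocol driver).
#' @param u0 initial displacement vector.
#' @param pars list of load parameters `eps_v, eps_fat, ICP, M, IOP`.
#' @param rtol,atol,maxit solver controls. The absolute floor `atol` (uN)
#'   reflects the irreducible deviatoric residual of the Lagrangian treatment
#'   of the near-inviscid tissues: relaxing it would require bulk fluid flow
#'   that a fixed mesh cannot represent, and it sits three orders of magnitude
#'   below the applied-load scale.
#' @return list with `u`, `converged`, `iterations`, `resid`, `info`.
#' @keywords internal
newton_solve <- function(ctx, u0, pars, p0 = NULL, rtol = 1e-8, atol = 8,
                         maxit = 140,
                         verbose = isTRUE(getOption("orbitfem.verbose"))) {
  u <- u0
  p <- if (is.null(p0)) numeric(ctx$np) else p0
  free <- setdiff(seq_len(ctx$ndof), ctx$fixed)
  a <- fe_assemble(ctx, u, pars, p)
  if (!a$ok) return(list(u = u, p = p, converged = FALSE, iterations = 0,
                         resid = Inf, info = NULL,
                         reason = sprintf("element inversion (element %d)", a$bad_elem)))
  rnorm_of <- function(a_) {
    rp2 <- 0
    for (blk in a_$mv) {
      rp <- blk$kap * blk$Rp / blk$V0^(2 / 3) # force-scaled constraint
      rp2 <- rp2 + sum(rp^2)
    }
    sqrt(sum(a_$R[free]^2) + rp2)
  }
  ref <- max(sqrt(sum(a$Fext^2)), sqrt(sum(a$R[free]^2)), 1)
  tol <- max(rtol * ref, atol)
  rn <- rnorm_of(a)
  if (!is.finite(rn))
    return(list(u = u, p = p, converged = FALSE, iterations = 0, resid = Inf,
                info = a$info, reason = "non-finite residual"))
  it <- 0
  # Pure Newton on the condensed mixed system with a trust-region-like cap on
  # the displacement increment (the volumetric constraints of the fluid-like
  # tissues are strongly nonlinear beyond ~0.5 mm moves) and a generous
  # transient-growth allowance; a small diagonal damping is enlisted only when
  # the plain step fails outright.
  cap <- 0.25
  lam <- 0
  best <- list(u = u, p = p, a = a, rn = rn)
  fails <- 0
  while (rn > tol && it < maxit) {
    it <- it + 1
    Kff <- a$K[free, free, drop = FALSE]
    Reff <- a$R + a$Radd
    Kd <- if (lam > 0) {
      dg <- pmax(Matrix::diag(Kff), 0)
      Kff + Matrix::Diagonal(x = lam * dg)
    } else Kff
    sol <- tryCatch(Matrix::solve(Kd, -Reff[free]), error = function(e) NULL)
    if (is.null(sol)) {
      lam <- max(lam * 100, 1e-6)
      fails <- fails + 1
      if (fails > 6)
        return(list(u = best$u, p = best$p, converged = FALSE,
                    iterations = it, resid = best$rn, info = best$a$info,
                    reason = "singular tangent"))
      next
    }
    du <- numeric(ctx$ndof)
    du[free] <- as.numeric(sol)
    dp <- pressure_update(ctx, a$mv, du)
    alpha <- min(1, cap / max(abs(du)))
    ok <- FALSE
    for (ls in 1:15) {
      a2 <- fe_assemble(ctx, u + alpha * du, pars, p + alpha * dp)
      if (a2$ok) {
        rn2 <- rnorm_of(a2)
        if (is.finite(rn2) && rn2 < 4 * rn) { ok <- TRUE; break }
      }
      alpha <- alpha / 2
    }
    if (!ok) {
      fails <- fails + 1
      lam <- max(lam * 100, 1e-6)
      cap <- cap / 2
      u <- best$u
      p <- best$p
      a <- best$a
      rn <- best$rn
      if (fails > 6)
        return(list(u = best$u, p = best$p, converged = FALSE,
                    iterations = it, resid = best$rn, info = best$a$info,
                    reason = "line search failed"))
      next
    }
    u <- u + alpha * du
    p <- p + alpha * dp
    a <- a2
    rn <- rn2
    if (rn < best$rn) best <- list(u = u, p = p, a = a, rn = rn)
    if (verbose)
      cat(sprintf("  newton it %2d resid %.4g alpha %.4g lam %.3g maxdu %.3g\n",
                  it, rn, alpha, lam, max(abs(du))))
    lam <- lam * 0.1
    if (lam < 1e-9) lam <- 0
  }
  if (rn > best$rn) {
    u <- best$u
    p <- best$p
    a <- best$a
    rn <- best$rn
  }
  list(u = u, p = p, converged = rn <= tol, iterations = it, resid = rn,
       info = a$info, Fext = a$Fext,
       reason = if (rn <= tol) "converged" else "max iterations")
}

#' Path-following continuation over a load schedule
#'
#' Solves one equilibrium per schedule row, seeding each solve with the
#' previous solution; a non-converged step is bisected (at most
#' `max_bisect` times).
#'
#' @param ctx solve context.
#' @param schedule data.frame with columns `eps_v, eps_fat, ICP, M, IOP`
#'   (monotone in each parameter).
#' @param u0 starting displacement.
#' @param pars0 parameters corresponding to `u0`.
#' @param max_bisect maximum number of bisections per step.
#' @return list of solution states (one per schedule row).
#' @keywords internal
step_continuation <- function(ctx, schedule, u0 = NULL, p0 = NULL,
                              pars0 = NULL, max_bisect = 10) {
  if (nrow(schedule) == 0) return(list())
  if (is.null(u0)) u0 <- numeric(ctx$ndof)
  if (is.null(p0)) p0 <- numeric(ctx$np)
  if (is.null(pars0)) pars0 <- list(eps_v = 0, eps_fat = 0, ICP = 0, M = 0, IOP = 0)
  states <- vector("list", nrow(schedule))
  u <- u0
  p <- p0
  prev <- pars0
  for (k in seq_len(nrow(schedule))) {
    target <- as.list(schedule[k, , drop = FALSE])
    res <- .advance(ctx, u, p, prev, target, max_bisect)
    if (!res$converged) {
      err <- structure(
        class = c("orbitfem_nonconvergence", "error", "condition"),
        list(message = sprintf(
          "step_continuation: failed at schedule row %d (%s); %d steps completed",
          k, res$reason, k - 1),
          call = sys.call(),
          states = states[seq_len(k - 1)], last = res))
      stop(err)
    }
    st <- list(u = res$u, p = res$p, pars = target, converged = TRUE,
               iterations = res$iterations, resid = res$resid,
               forces = res$info[c("F_ICP", "F_fat", "F_EOM", "F_ON")],
               w_insertion = res$info$w_insertion,
               W = res$info$W, E_contact = res$info$E_contact,
               gaps = res$info$gaps, pn = res$info$pn, Fext = res$Fext)
    class(st) <- "solution_state"
    states[[k]] <- st
    u <- res$u
    p <- res$p
    prev <- target
  }
  states
}

# advance from pars a to b, bisecting recursively on failure
.advance <- function(ctx, u, p, a, b, depth) {
  res <- newton_solve(ctx, u, b, p0 = p)
  if (res$converged) return(res)
  if (depth <= 0) return(res)
  mid <- Map(function(x, y) (x + y) / 2, a, b)
  r1 <- .advance(ctx, u, p, a, mid, depth - 1)
  if (!r1$converged) return(r1)
  .advance(ctx, r1$u, r1$p, mid, b, depth - 1)
}

#' Solve a single equilibrium on a mesh (module-level entry point)
#'
#' Thin wrapper assembling a solve context from mesh, tissue registry and a
#' load case at fixed parameter values.
#'
#' @param mesh a `mesh_model` (eye-only or combined).
#' @param tissues a [tissue_registry()].
#' @param loads a [load_case()].
#' @param pars list `eps_v, eps_fat, ICP, M, IOP` (missing entries default 0).
#' @param initial_guess optional displacement vector.
#' @param ... passed to `solve_context` (e.g. `pin`, `direct_iop`).
#' @return a solution state (list with `u`, convergence metadata, forces).
#' @export
solve_equilibrium <- function(mesh, tissues, loads, pars = list(),
                              initial_guess = NULL, ...) {
  stage <- if (mesh$component == "combined") "orbit" else "eye"
  ctx <- solve_context(mesh, tissues, loads, stage = stage, ...)
  dflt <- list(eps_v = 0, eps_fat = 0, ICP = 0, M = 0, IOP = 0)
  pars <- modifyList(dflt, pars)
  if (is.null(initial_guess)) initial_guess <- numeric(ctx$ndof)
  res <- newton_solve(ctx, initial_guess, pars)
  if (!res$converged)
    stop("solve_equilibrium: no convergence (", res$reason,
         "), residual ", format(res$resid))
  st <- list(u = res$u, p = res$p, pars = pars, converged = TRUE,
             iterations = res$iterations, resid = res$resid,
             forces = res$info[c("F_ICP", "F_fat", "F_EOM", "F_ON")],
             W = res$info$W, E_contact = res$info$E_contact,
             gaps = res$info$gaps, pn = res$info$pn, Fext = res$Fext)
  class(st) <- "solution_state"
  st
}

#' Per-element volume-averaged fields at a state
#'
#' Returns reference volume, total and elastic volume ratios (`J`, `J/J_H`),
#' hydrostatic Cauchy stress and energy density per element.
#'
#' @param mesh a `mesh_model`.
#' @param tissues a [tissue_registry()].
#' @param u displacement vector.
#' @param eps_v,eps_fat current swelling strains.
#' @return matrix with columns `vol, J, Je, hydro, W`.
#' @export
element_fields <- function(mesh, tissues, u, eps_v = 0, eps_fat = 0) {
  out <- NULL
  for (nm in names(mesh$blocks)) {
    b <- mesh$blocks[[nm]]
    mat <- material_rows_block(b$region, tissues, (1 + eps_v)^3, (1 + eps_fat)^3)
    tab <- basis_tables(b$order)
    ef <- elem_fields_cpp(mesh$nodes, b$elems, cbind(mat[, 1], 0, mat[, 3]),
                          u, tab$mid)
    fl <- b$region %in% c(2L, 3L)
    Jb <- numeric(ncol(b$elems))
    if (any(!fl)) {
      mdS <- asm_meandil_cpp(mesh$nodes, b$elems[, !fl, drop = FALSE],
                             cbind(mat[!fl, 2], mat[!fl, 3]), u, tab$mid)
      Jb[!fl] <- mdS$Jbar
    }
    if (any(fl)) {
      mdF <- asm_mixedvol_cpp(mesh$nodes, b$elems[, fl, drop = FALSE],
                              cbind(mat[fl, 2], mat[fl, 3]),
                              u, numeric(sum(fl)), tab$vedge_idx, tab$vedge)
      Jb[fl] <- mdF$Jbar
    }
    JH <- mat[, 3]
    ef[, "Je"] <- Jb / JH
    ef[, "hydro"] <- ef[, "hydro"] + mat[, 2] * (Jb - JH) / JH
    ef[, "W"] <- ef[, "W"] + mat[, 2] / 2 * ((Jb - JH) / JH)^2
    ef <- cbind(ef, region = b$region)
    out <- rbind(out, ef)
  }
  out
}

#' Frictionless contact interface report
#'
#' Evaluates gaps and normal pressures on the sclera-fat interface at a state.
#' Tangential traction transfer is identically zero by construction (forces
#' act along the smooth master-surface normal only).
#'
#' @param mesh combined `mesh_model`.
#' @param u displacement vector.
#' @param kp penalty stiffness (Pa/mm).
#' @return data.frame with slave node id, gap (mm) and normal pressure (Pa).
#' @export
contact_interface <- function(mesh, u = numeric(2 * nrow(mesh$nodes)),
                              kp = 1e7) {
  sub_phi <- edge_basis_eval(mesh$order, seq(0, 1, length.out = 6))$phi
  ns <- length(mesh$contact$slave)
  cc <- asm_contact_cpp(mesh$nodes, u, mesh$contact$slave,
                        mesh$contact$slave_w, mesh$contact$master_edges,
                        sub_phi, edge_basis_coeffs(mesh$order), kp, 0.02,
                        integer(ns), integer(ns), numeric(ns))
  data.frame(node = mesh$contact$slave, gap = cc$gap, pressure = cc$pn,
             tangential = 0)
}
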