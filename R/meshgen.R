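# Structured multi-region mesh generation for the axisymmetric eye/orbit
# model. Each region is meshed by a mapped grid; regions that are tied
# (shell-vitreous, shell-bundle, shell-dura) share node coordinates exactly and
# are merged into one conforming mesh, while the orbital fat is meshed
# independently (non-conforming) and coupled through sliding contact.

REGION_NAMES <- c("ocular_coats", "vitreous", "orbital_fat", "axon_bundle", "dura")

# --- small helpers ----------------------------------------------------------

.coord_key <- function(x) paste(sprintf("%.7f", x[, 1]), sprintf("%.7f", x[, 2]))

# triangles (3 x n) from a grid of node ids idx[i, j]; degenerate cells where
# two corners share an id collapse to single triangles
grid_tris <- function(idx) {
  ni <- nrow(idx); nj <- ncol(idx)
  out <- vector("list", (ni - 1) * (nj - 1))
  k <- 1L
  for (i in seq_len(ni - 1)) {
    for (j in seq_len(nj - 1)) {
      n00 <- idx[i, j]; n10 <- idx[i + 1, j]
      n11 <- idx[i + 1, j + 1]; n01 <- idx[i, j + 1]
      cs <- unique(c(n00, n10, n11, n01))
      if (length(cs) == 4) {
        out[[k]] <- cbind(c(n00, n10, n11), c(n00, n11, n01))
      } else if (length(cs) == 3) {
        out[[k]] <- matrix(cs, 3, 1)
      }
      k <- k + 1L
    }
  }
  do.call(cbind, out[!vapply(out, is.null, logical(1))])
}

orient_tris <- function(nodes, tris) {
  x <- nodes[, 1]; y <- nodes[, 2]
  a <- tris[1, ]; b <- tris[2, ]; c3 <- tris[3, ]
  ar <- (x[b] - x[a]) * (y[c3] - y[a]) - (x[c3] - x[a]) * (y[b] - y[a])
  flip <- which(ar < 0)
  if (length(flip)) tris[2:3, flip] <- tris[3:2, flip]
  tris
}

min_angle_deg <- function(nodes, tris) {
  ang <- function(p, q, r) {
    v1 <- q - p; v2 <- r - p
    acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1))
  }
  m <- Inf
  for (e in seq_len(ncol(tris))) {
    P <- nodes[tris[, e], , drop = FALSE]
    m <- min(m, ang(P[1, ], P[2, ], P[3, ]), ang(P[2, ], P[3, ], P[1, ]),
             ang(P[3, ], P[1, ], P[2, ]))
  }
  m * 180 / pi
}

# merge a list of patches (nodes, tris, region, curve, param, chains = named
# list of local id vectors) into one linear (T3) mesh
merge_patches <- function(patches) {
  all_nodes <- do.call(rbind, lapply(patches, `[[`, "nodes"))
  keys <- .coord_key(all_nodes)
  uk <- !duplicated(keys)
  gid <- match(keys, keys[uk])
  nodes <- all_nodes[uk, , drop = FALSE]
  curve <- rep(NA_character_, nrow(nodes))
  param <- rep(NA_real_, nrow(nodes))
  tris <- NULL; region <- NULL
  chains <- list()
  off <- 0L
  for (p in patches) {
    n <- nrow(p$nodes)
    map <- gid[off + seq_len(n)]
    tris <- cbind(tris, matrix(map[p$tris], 3))
    region <- c(region, rep(p$region, ncol(p$tris)))
    if (!is.null(p$curve)) {
      set <- !is.na(p$curve) & is.na(curve[map])
      curve[map[set]] <- p$curve[set]
      param[map[set]] <- p$param[set]
    }
    for (nm in names(p$chains)) chains[[nm]] <- map[p$chains[[nm]]]
    off <- off + n
  }
  tris <- orient_tris(nodes, tris)
  list(nodes = nodes, tris = tris, region = region, curve = curve,
       param = param, chains = chains)
}

# elevate a T3 mesh to Lagrange order p; nodes on tagged curves are placed on
# the exact curve by parameter interpolation
elevate_mesh <- function(m, p, curve_registry) {
  lat <- tri_lattice(p) # (xi, eta) fractions; lambda = (1-xi-eta, xi, eta)
  nlat <- nrow(lat)
  E <- ncol(m$tris)
  nodes <- m$nodes
  curve <- m$curve
  param <- m$param
  edge_env <- new.env(hash = TRUE, size = 4 * nrow(nodes))
  elems <- matrix(0L, nlat, E)
  nodes_extra <- list(); curve_extra <- character(); param_extra <- numeric()
  nextid <- nrow(nodes)
  new_node <- function(xy, cv = NA_character_, pm = NA_real_) {
    nextid <<- nextid + 1L
    nodes_extra[[length(nodes_extra) + 1L]] <<- xy
    curve_extra[length(curve_extra) + 1L] <<- cv
    param_extra[length(param_extra) + 1L] <<- pm
    nextid
  }
  edge_node <- function(a, b, k) {
    # node at fraction k/p of the way from a to b
    if (a > b) return(edge_node(b, a, p - k))
    key <- paste(a, b, k)
    id <- edge_env[[key]]
    if (!is.null(id)) return(id)
    wa <- 1 - k / p; wb <- k / p
    cv <- NA_character_; pm <- NA_real_
    if (!is.na(curve[a]) && !is.na(curve[b]) && curve[a] == curve[b]) {
      cv <- curve[a]
      pm <- wa * param[a] + wb * param[b]
      xy <- curve_registry[[cv]](pm)
    } else {
      xy <- wa * nodes[a, ] + wb * nodes[b, ]
    }
    id <- new_node(as.numeric(xy), cv, pm)
    edge_env[[key]] <- id
    id
  }
  for (e in seq_len(E)) {
    cn <- m$tris[, e]
    for (l in seq_len(nlat)) {
      lam <- c(1 - lat[l, 1] - lat[l, 2], lat[l, 1], lat[l, 2])
      nz <- which(lam > 1e-12)
      if (length(nz) == 1) {
        elems[l, e] <- cn[nz]
      } else if (length(nz) == 2) {
        a <- cn[nz[1]]; b <- cn[nz[2]]
        elems[l, e] <- edge_node(a, b, round(lam[nz[2]] * p))
      } else {
        # interior node: transfinite blend so curved (snapped) edges carry
        # their curvature into the element interior (plain barycentric
        # placement folds high-order maps in strongly curved elements)
        xy <- lam[1] * nodes[cn[1], ] + lam[2] * nodes[cn[2], ] + lam[3] * nodes[cn[3], ]
        pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
        for (pr in pairs) {
          a <- cn[pr[1]]; b <- cn[pr[2]]
          if (!is.na(curve[a]) && !is.na(curve[b]) && curve[a] == curve[b]) {
            t <- lam[pr[2]] / (lam[pr[1]] + lam[pr[2]])
            pm <- (1 - t) * param[a] + t * param[b]
            dev <- curve_registry[[curve[a]]](pm) -
              ((1 - t) * nodes[a, ] + t * nodes[b, ])
            xy <- xy + (lam[pr[1]] + lam[pr[2]]) * dev
          }
        }
        elems[l, e] <- new_node(as.numeric(xy))
      }
    }
  }
  if (length(nodes_extra)) {
    nodes <- rbind(nodes, do.call(rbind, nodes_extra))
    curve <- c(curve, curve_extra)
    param <- c(param, param_extra)
  }
  list(nodes = nodes, elems = elems, curve = curve, param = param,
       edge_node = NULL,
       edge_nodes_between = function(a, b) {
    if (p == 1) return(integer(0))
    ids <- integer(p - 1)
    for (k in seq_len(p - 1)) {
      key <- if (a > b) paste(b, a, p - k) else paste(a, b, k)
      id <- edge_env[[key]]
      if (is.null(id)) stop("elevate_mesh: missing edge node (chain off-mesh)")
      ids[k] <- id
    }
    ids
  })
}

# expand a corner chain to the elevated chain and per-edge connectivity
chain_expand <- function(chain, ev, p) {
  n <- length(chain)
  if (n < 2) return(list(nodes = chain, edges = matrix(0L, p + 1, 0)))
  edges <- matrix(0L, p + 1, n - 1)
  full <- chain[1]
  for (k in seq_len(n - 1)) {
    a <- chain[k]; b <- chain[k + 1]
    mids <- ev$edge_nodes_between(a, b)
    edges[, k] <- c(a, mids, b)
    full <- c(full, mids, b)
  }
  list(nodes = full, edges = edges)
}

# --- region generators (T3 patches) ----------------------------------------

.theta_grid <- function(geom, m) {
  bp <- c(0, geom$insertion_theta, pi / 2, 3 * pi / 4, pi - pi / 8,
          geom$theta_sas1, geom$theta_RDo, geom$theta_RDi, geom$theta_cut)
  if (is.unsorted(bp, strictly = TRUE))
    stop("mesh_geometry: meshing failure in region ocular_coats ",
         "(posterior feature angles out of order)")
  base <- c(8, 5, 8, 7, 6, 3, 2, 1)
  scalable <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  n <- ifelse(scalable, pmax(1, round(base * m)), base)
  th <- 0
  for (k in seq_along(n))
    th <- c(th, seq(bp[k], bp[k + 1], length.out = n[k] + 1)[-1])
  th
}

gen_shell <- function(geom, m, nt) {
  th <- .theta_grid(geom, m)
  K <- length(th)
  tt <- seq(0, 1, length.out = nt + 1)
  Ins <- geom$curves$inner_ell(th)
  Outs <- geom$curves$outer_ell(th)
  # last station: vertical canal cut at r = R_A
  Outs[K, ] <- c(geom$params$R_A, geom$z_out_r(geom$params$R_A))
  nn <- K * (nt + 1)
  nodes <- matrix(0, nn, 2)
  idx <- matrix(seq_len(nn), K, nt + 1)
  for (j in seq_len(nt + 1))
    nodes[idx[, j], ] <- (1 - tt[j]) * Ins + tt[j] * Outs
  curve <- rep(NA_character_, nn)
  param <- rep(NA_real_, nn)
  curve[idx[, 1]] <- "inner_ell"; param[idx[, 1]] <- th
  th_out <- th
  th_out[K] <- pi - asin(geom$params$R_A / geom$a_o)
  curve[idx[, nt + 1]] <- "outer_ell"; param[idx[, nt + 1]] <- th_out
  list(nodes = nodes, tris = grid_tris(idx), region = 1L,
       curve = curve, param = param,
       chains = list(shell_inner = idx[, 1], shell_outer = idx[, nt + 1],
                     canal_face = idx[K, ]),
       theta = th, theta_out = th_out)
}

gen_vitreous <- function(geom, m, shell_theta, disc_theta) {
  thb <- c(shell_theta, disc_theta[-1]) # full 0..pi boundary parameters
  nb <- length(thb)
  K <- max(3, round(4 * m))
  s <- 1 - (seq_len(K) / (K + 1))^1.2 # ring scales (boundary excluded)
  C <- c(0, geom$zc)
  th_uni <- seq(0, pi, length.out = nb)
  nn <- nb * (K + 1) + 1
  nodes <- matrix(0, nn, 2)
  idx <- matrix(seq_len(nb * (K + 1)), nb, K + 1)
  B <- geom$curves$inner_ell(thb)
  B[abs(B[, 1]) < 1e-12, 1] <- 0
  nodes[idx[, 1], ] <- B
  for (k in seq_len(K)) {
    # relax the angular grid toward uniform away from the boundary so the
    # tiny posterior (canal-side) intervals do not propagate inward
    w <- sqrt(k / (K + 1))
    thk <- (1 - w) * thb + w * th_uni
    Q <- geom$curves$inner_ell(thk)
    nodes[idx[, k + 1], ] <- cbind(C[1] + s[k] * (Q[, 1] - C[1]),
                                   C[2] + s[k] * (Q[, 2] - C[2]))
  }
  nodes[abs(nodes[, 1]) < 1e-12, 1] <- 0
  nodes[nn, ] <- C
  tris <- grid_tris(idx)
  fan <- rbind(rep(nn, nb - 1), idx[1:(nb - 1), K + 1], idx[2:nb, K + 1])
  curve <- rep(NA_character_, nn)
  param <- rep(NA_real_, nn)
  curve[idx[, 1]] <- "inner_ell"; param[idx[, 1]] <- thb
  list(nodes = nodes, tris = cbind(tris, fan), region = 2L,
       curve = curve, param = param, chains = list())
}

gen_bundle <- function(geom, m, disc_theta, nt_shell) {
  RA <- geom$params$R_A
  rcols <- rev(geom$a_i * sin(disc_theta)) # 0 .. R_A
  rcols[1] <- 0
  rcols[length(rcols)] <- RA
  ztopA <- geom$z_in_r(RA)
  zbotA <- geom$z_out_r(RA)
  # normalised heights; include the canal-face layers at r = R_A for conformity
  zf <- ((1 - seq(0, 1, length.out = nt_shell + 1)) * ztopA +
           seq(0, 1, length.out = nt_shell + 1) * zbotA) / ztopA
  nz <- max(4, round(6 * m))
  zeta <- sort(unique(c(seq(0, min(zf), length.out = nz + 1), zf)))
  nc <- length(rcols); nl <- length(zeta)
  nodes <- matrix(0, nc * nl, 2)
  idx <- matrix(seq_len(nc * nl), nc, nl)
  for (j in seq_len(nl))
    nodes[idx[, j], ] <- cbind(rcols, zeta[j] * geom$z_in_r(rcols))
  curve <- rep(NA_character_, nc * nl)
  param <- rep(NA_real_, nc * nl)
  curve[idx[, nl]] <- "inner_ell"
  param[idx[, nl]] <- rev(disc_theta)
  list(nodes = nodes, tris = grid_tris(idx), region = 4L,
       curve = curve, param = param,
       chains = list(bundle_bottom = idx[, 1],
                     disc = rev(idx[, nl]))) # ordered R_A -> 0
}

gen_dura <- function(geom, m, theta_out) {
  # columns matching the shell outer stations between theta_RDo and theta_RDi
  th_att <- theta_out[theta_out >= geom$theta_RDo - 1e-12 &
                        theta_out <= geom$theta_RDi + 1e-12]
  rcols <- sort(geom$a_o * sin(th_att)) # R_Di .. R_Do
  nzd <- max(5, round(8 * m))
  eta <- seq(0, 1, length.out = nzd + 1)
  nc <- length(rcols); nl <- length(eta)
  nodes <- matrix(0, nc * nl, 2)
  idx <- matrix(seq_len(nc * nl), nc, nl)
  for (j in seq_len(nl))
    nodes[idx[, j], ] <- cbind(rcols, eta[j] * geom$z_out_r(rcols))
  curve <- rep(NA_character_, nc * nl)
  param <- rep(NA_real_, nc * nl)
  curve[idx[, nl]] <- "outer_ell"
  param[idx[, nl]] <- pi - asin(rcols / geom$a_o)
  list(nodes = nodes, tris = grid_tris(idx), region = 5L,
       curve = curve, param = param,
       chains = list(dura_outer = idx[nc, ], # bottom -> top at r = R_Do
                     dura_bottom = idx[, 1]))
}

# arclength table of the outer ellipse between two polar angles
.ell_arc <- function(geom, th0, th1, n = 2000) {
  th <- seq(th0, th1, length.out = n)
  P <- geom$curves$outer_ell(th)
  ds <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  list(theta = th, s = c(0, cumsum(ds)))
}

# default (analytic) fat inner boundary: dura outer side, then the outer globe
# surface around to the rim plane
.fat_inner_default <- function(geom) {
  p <- geom$params
  zda <- geom$z_out_r(p$R_Do)
  dura <- cbind(p$R_Do, seq(0, zda, length.out = 80)[-80])
  arc <- .ell_arc(geom, geom$theta_RDo, geom$theta_exit, n = 800)
  pts <- rbind(dura, geom$curves$outer_ell(arc$theta))
  list(pts = pts, L_dura = zda)
}

# replace the concave dura-globe attachment corner of the fat inner boundary
# by a straight chord (half-length f): the corner otherwise traps fat between
# two converging contact faces as the globe advances. The excluded wedge is a
# few mm^3 out of ~10^4.
.fillet_corner <- function(pts, L_dura, f = 3) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  svec <- c(0, cumsum(seg))
  s0 <- L_dura - f
  s1 <- L_dura + f
  if (s0 <= 0 || s1 >= max(svec)) return(list(pts = pts, L_dura = L_dura))
  P0 <- c(approx(svec, pts[, 1], s0)$y, approx(svec, pts[, 2], s0)$y)
  P1 <- c(approx(svec, pts[, 1], s1)$y, approx(svec, pts[, 2], s1)$y)
  keep_lo <- svec < s0
  keep_hi <- svec > s1
  chord <- cbind(seq(P0[1], P1[1], length.out = 9),
                 seq(P0[2], P1[2], length.out = 9))
  newpts <- rbind(pts[keep_lo, , drop = FALSE], chord,
                  pts[keep_hi, , drop = FALSE])
  list(pts = newpts, L_dura = s0)
}

gen_fat <- function(geom, m, inner = NULL) {
  p <- geom$params
  if (is.null(inner)) inner <- .fat_inner_default(geom)
  inner <- .fillet_corner(inner$pts, inner$L_dura)
  pts <- inner$pts
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  svec <- c(0, cumsum(seg))
  L_in <- max(svec)
  s_att <- inner$L_dura / L_in
  Pin <- function(s) cbind(approx(svec, pts[, 1], xout = s * L_in, rule = 2)$y,
                           approx(svec, pts[, 2], xout = s * L_in, rule = 2)$y)
  wall_r <- geom$wall_r
  n1 <- max(3, round(5 * m))
  n2 <- max(22, round(34 * m))
  # the fat starts a few mm above the orbital apex: the thin wedge between the
  # nerve sheath and the converging wall pins the sliding nerve numerically
  # and carries a negligible share of the fat volume
  z_base <- 3
  s_base <- approx(pts[, 2], svec, xout = z_base, ties = min)$y / L_in
  svals <- c(seq(s_base, s_att, length.out = n1 + 1),
             seq(s_att, 1, length.out = n2 + 1)[-1])
  inner_xy <- Pin(svals[-1])
  inner_s <- svals[-1] * L_in
  # horizontal layers: every station spans from the inner boundary to the wall
  # at the same height, so the mapped grid can never fold; stations whose
  # height step is tiny (near the globe equator) are dropped. The exit channel
  # (last few mm below the rim) keeps finer spacing: the fat extrudes through
  # it and carries the largest strains.
  zrow <- inner_xy[, 2]
  keep <- rep(TRUE, length(zrow))
  zlast <- 0
  for (i in seq_along(zrow)) {
    if (i < length(zrow) && zrow[i] - zlast < 0.3 / m) keep[i] <- FALSE
    else zlast <- zrow[i]
  }
  inner_xy <- inner_xy[keep, , drop = FALSE]
  inner_s <- inner_s[keep]
  ns <- nrow(inner_xy)
  ntf <- max(5, round(5 * m))
  tt <- seq(0, 1, length.out = ntf + 1)
  nn <- ns * (ntf + 1)
  nodes <- matrix(0, nn, 2)
  idx <- matrix(seq_len(nn), ns, ntf + 1)
  outer_r <- wall_r(inner_xy[, 2])
  for (j in seq_len(ntf + 1))
    nodes[idx[, j], ] <- cbind((1 - tt[j]) * inner_xy[, 1] + tt[j] * outer_r,
                               inner_xy[, 2])
  curve <- rep(NA_character_, nn)
  param <- rep(NA_real_, nn)
  # inner-boundary nodes are snapped along the (possibly deformed) boundary
  # polyline, parameterised by arclength
  onb <- inner_s > inner$L_dura * (1 - 1e-9)
  curve[idx[, 1][onb]] <- "fat_inner"
  param[idx[, 1][onb]] <- inner_s[onb]
  attr(nodes, "fat_inner_curve") <- function(t)
    c(approx(svec, pts[, 1], xout = t, rule = 2)$y,
      approx(svec, pts[, 2], xout = t, rule = 2)$y)
  list(nodes = nodes, tris = grid_tris(idx), region = 3L,
       curve = curve, param = param,
       chains = list(fat_inner = idx[, 1],
                     fat_wall = idx[, ntf + 1],
                     fat_free = idx[ns, ]))
}

# --- top-level meshing ------------------------------------------------------

.density_mult <- function(density) {
  if (is.numeric(density)) {
    if (density <= 0) stop("mesh_geometry: density must be positive")
    return(1.1 / density) # interpret as target edge length (mm)
  }
  switch(match.arg(density, c("coarse", "medium", "fine")),
         coarse = 1, medium = 1.5, fine = 2.25)
}

#' Mesh the eye (shell + vitreous + axon bundle + dura), conforming
#'
#' @param geom a `geometry_model`; for zero-stress configurations build it from
#'   the zero-stress radii.
#' @param density `"coarse"`, `"medium"`, `"fine"`, or a target edge length
#'   (mm).
#' @param order Lagrange element order (1, 2 or 4; default 2).
#' @return a `mesh_model`.
#' @export
mesh_eye <- function(geom, density = "coarse", order = 2) {
  m <- .density_mult(density)
  # through-thickness layers: high-order elements carry the thickness
  # interpolation themselves
  nt <- if (order >= 3) 2 else max(3, round(3 * m))
  sh <- gen_shell(geom, m, nt)
  nd <- max(2, round(2 * m) + 1)
  disc_theta <- seq(geom$theta_cut, pi, length.out = nd + 1)
  vi <- gen_vitreous(geom, m, sh$theta, disc_theta)
  bu <- gen_bundle(geom, m, disc_theta, nt)
  du <- gen_dura(geom, m, sh$theta_out)
  mm <- merge_patches(list(sh, vi, bu, du))
  finish_mesh(mm, geom, order, component = "eye",
              extra = list(theta = sh$theta, theta_out = sh$theta_out))
}

#' Mesh the orbital fat (independent, non-conforming with the eye)
#'
#' @inheritParams mesh_eye
#' @param inner optional deformed inner boundary: list with `pts` (polyline
#'   from the dura foot up and around the globe to the rim plane) and
#'   `L_dura` (arclength of the dura section). The staged protocol builds the
#'   fat against the deformed Model-B surface so that fat and eye are in
#'   contact at rest.
#' @return a `mesh_model`.
#' @export
mesh_fat <- function(geom, density = "coarse", order = 2, inner = NULL) {
  m <- .density_mult(density)
  fa <- gen_fat(geom, m, inner = inner)
  curve_fn <- attr(fa$nodes, "fat_inner_curve")
  mm <- merge_patches(list(fa))
  finish_mesh(mm, geom, order, component = "fat",
              extra = list(fat_inner_curve = curve_fn))
}

finish_mesh <- function(mm, geom, order, component, extra) {
  curve_registry <- list(
    inner_ell = function(t) geom$curves$inner_ell(t)[1, ],
    outer_ell = function(t) geom$curves$outer_ell(t)[1, ],
    fat_inner = extra$fat_inner_curve
  )
  quality <- min_angle_deg(mm$nodes, mm$tris)
  ev <- elevate_mesh(mm, order, curve_registry)
  chains <- list()
  chain_edges <- list()
  for (nm in names(mm$chains)) {
    ce <- chain_expand(mm$chains[[nm]], ev, order)
    chains[[nm]] <- ce$nodes
    chain_edges[[nm]] <- ce$edges
  }
  nodes <- ev$nodes
  nodes[abs(nodes[, 1]) < 1e-9, 1] <- 0
  sets <- list(axis = which(nodes[, 1] == 0))
  if (component == "eye") {
    th_out <- extra$theta_out
    outer_ids <- chains$shell_outer
    # corner index of the insertion ring on the outer surface
    ins_corner <- which.min(abs(extra$theta_out - geom$insertion_theta))
    ins_id <- mm$chains$shell_outer[ins_corner]
    sets$insertion <- ins_id
    sets$anterior_pole <- mm$chains$shell_outer[1]
    sets$disc_center <- mm$chains$disc[length(mm$chains$disc)]
    sets$apex <- mm$chains$bundle_bottom[1] # r = 0, z = 0
    # master polyline: dura outer bottom->top, then outer shell from the
    # attach angle forward (theta decreasing) to the anterior pole
    katt <- which.min(abs(th_out - geom$theta_RDo))
    shell_part_corners <- mm$chains$shell_outer[katt:1]
    master_c <- c(mm$chains$dura_outer, shell_part_corners[-1])
    sets$n_dura_edges <- length(mm$chains$dura_outer) - 1L
    cem <- chain_expand(master_c, ev, order)
    chains$master <- cem$nodes
    chain_edges$master <- cem$edges
    # ICP application surfaces, ordered posterior -> anterior (theta
    # decreasing, sclera on the left).
    # Default: the roof of the sub-arachnoid space (the scleral flange face
    # between the canal and the inner dura radius), whose projected annulus
    # reproduces the quoted terrestrial ICP resultant.
    in_roof <- which(th_out >= geom$theta_RDi - 1e-12)
    chain_edges$sas_band <- chain_expand(mm$chains$shell_outer[rev(in_roof)],
                                         ev, order)$edges
    # Alternative reading: a 270-um annulus of the outer sclera beginning at
    # the outer dural radius.
    in_band <- which(th_out >= geom$theta_sas1 - 1e-12 &
                       th_out <= geom$theta_RDo + 1e-12)
    band_corners <- mm$chains$shell_outer[rev(in_band)]
    chain_edges$sas_band_outer <- chain_expand(band_corners, ev, order)$edges
    # direct-IOP surface: inner shell (anterior->posterior) + disc (R_A -> 0)
    ce_in <- chain_expand(mm$chains$shell_inner, ev, order)$edges
    ce_disc <- chain_expand(mm$chains$disc, ev, order)$edges
    chain_edges$iop_surface <- cbind(ce_in, ce_disc)
    # inner-sclera arc-length chain with polar-angle labels
    ci <- chain_expand(mm$chains$shell_inner, ev, order)
    chains$inner_sclera <- ci$nodes
    chain_edges$inner_sclera <- ci$edges
    sets$inner_theta <- ev$param[ci$nodes]
    co <- chain_expand(mm$chains$shell_outer, ev, order)
    chains$outer_sclera <- co$nodes
    chain_edges$outer_sclera <- co$edges
    sets$outer_theta <- ev$param[co$nodes]
  } else {
    cf <- chain_expand(mm$chains$fat_inner, ev, order)
    chains$fat_inner <- cf$nodes
    chain_edges$fat_inner <- cf$edges
    sets$wall <- chain_expand(mm$chains$fat_wall, ev, order)$nodes
    sets$free <- chain_expand(mm$chains$fat_free, ev, order)$nodes
  }
  out <- list(nodes = nodes, elems = ev$elems, region = mm$region,
              blocks = list(main = list(elems = ev$elems, region = mm$region,
                                        order = order)),
              region_names = REGION_NAMES, order = order,
              curve = ev$param, node_curve = ev$curve,
              chains = chains, chain_edges = chain_edges, sets = sets,
              component = component, quality = quality,
              geom_hash = geometry_hash(geom))
  class(out) <- "mesh_model"
  out
}

#' Mesh the full model
#'
#' Builds the conforming eye mesh and the independent fat mesh and combines
#' them into one system with a sliding-contact interface. Mesh refinement
#' (`density`) strictly increases node count; element quality (minimum corner
#' angle of the generating triangulation) is reported in `$quality`.
#'
#' @param geom a `geometry_model` from [build_anatomy()]. For staged runs the
#'   eye may use a different (zero-stress) geometry: see [combine_meshes()].
#' @inheritParams mesh_eye
#' @return a combined `mesh_model` with `$contact` (master/slave info).
#' @export
mesh_geometry <- function(geom, density = "coarse", order = 2) {
  combine_meshes(mesh_eye(geom, density, order),
                 mesh_fat(geom, density, order))
}

#' Combine an eye mesh and a fat mesh into one contact-coupled system
#'
#' @param eye,fat `mesh_model`s from [mesh_eye()] and [mesh_fat()].
#' @return a combined `mesh_model`.
#' @export
combine_meshes <- function(eye, fat) {
  stopifnot(eye$component == "eye", fat$component == "fat")
  off <- nrow(eye$nodes)
  nodes <- rbind(eye$nodes, fat$nodes)
  chains <- c(eye$chains, lapply(fat$chains, `+`, off))
  chain_edges <- c(eye$chain_edges, lapply(fat$chain_edges, `+`, off))
  sets <- eye$sets
  sets$axis <- c(eye$sets$axis, fat$sets$axis + off)
  sets$wall <- fat$sets$wall + off
  sets$free <- fat$sets$free + off
  # slave nodes: fat inner chain minus wall-fixed pinch node
  sw <- slave_weights(fat, fat$chain_edges$fat_inner, fat$order)
  keep <- !(chains$fat_inner %in% sets$wall)
  slave <- chains$fat_inner[keep]
  # element blocks may differ in polynomial order (e.g. quartic eye for the
  # bending-dominated shell, quadratic fat)
  blocks <- list(
    eye = list(elems = eye$elems, region = eye$region, order = eye$order),
    fat = list(elems = fat$elems + off, region = fat$region, order = fat$order)
  )
  out <- list(nodes = nodes, blocks = blocks,
              region_names = REGION_NAMES, order = eye$order,
              chains = chains, chain_edges = chain_edges, sets = sets,
              component = "combined",
              quality = min(eye$quality, fat$quality),
              n_eye = off,
              contact = list(master_edges = chain_edges$master, slave = slave,
                             slave_w = sw[keep]),
              geom_hash = eye$geom_hash)
  class(out) <- "mesh_model"
  out
}

# consistent lumped tributary lengths (mm) of the fat inner-chain nodes, from
# reference coordinates; returns a vector aligned with the chain node order
slave_weights <- function(fat, edges, order) {
  eb <- edge_basis_table(order)
  chain <- fat$chains$fat_inner
  w <- setNames(numeric(length(chain)), as.character(chain))
  for (k in seq_len(ncol(edges))) {
    ids <- edges[, k]
    X <- fat$nodes[ids, , drop = FALSE]
    for (q in seq_along(eb$w)) {
      dr <- sum(eb$dphi[, q] * X[, 1])
      dz <- sum(eb$dphi[, q] * X[, 2])
      ds <- sqrt(dr^2 + dz^2)
      w[as.character(ids)] <- w[as.character(ids)] + eb$w[q] * eb$phi[, q] * ds
    }
  }
  unname(w[as.character(chain)])
}

#' @exportS3Method base::print
print.mesh_model <- function(x, ...) {
  ne <- sum(vapply(x$blocks, function(b) ncol(b$elems), 1))
  cat(sprintf("<mesh_model> %s: %d nodes, %d elements, min angle %.1f deg\n",
              x$component, nrow(x$nodes), ne, x$quality))
  rg <- unlist(lapply(x$blocks, `[[`, "region"))
  tab <- table(factor(x$region_names[rg], levels = x$region_names))
  print(tab[tab > 0])
  invisible(x)
}
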