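# Lagrange triangle bases on the reference triangle (xi, eta), vertices
# (0,0), (1,0), (0,1). Nodes sit on the barycentric lattice of order p,
# enumerated j = 0..p (eta rows), i = 0..(p - j). The same enumeration is used
# by the mesh elevation code, keeping basis and connectivity in step for any
# polynomial order.

tri_lattice <- function(p) {
  pts <- NULL
  for (j in 0:p) for (i in 0:(p - j)) pts <- rbind(pts, c(i, j))
  pts / p
}

.mono_exps <- function(p) {
  ex <- NULL
  for (j in 0:p) for (i in 0:(p - j)) ex <- rbind(ex, c(i, j))
  ex
}

# coefficient matrix of the nodal basis: phi_k = sum_l C[l,k] xi^a_l eta^b_l
tri_basis_coeffs <- function(p) {
  pts <- tri_lattice(p)
  ex <- .mono_exps(p)
  V <- outer(seq_len(nrow(pts)), seq_len(nrow(ex)),
             Vectorize(function(k, l) pts[k, 1]^ex[l, 1] * pts[k, 2]^ex[l, 2]))
  list(C = solve(V), ex = ex)
}

# evaluate basis values and derivatives at points (n x 2);
# returns nen x npts matrices (layout expected by the C++ kernels)
tri_basis_eval <- function(p, pts) {
  bc <- tri_basis_coeffs(p)
  ex <- bc$ex
  n <- nrow(pts)
  m <- nrow(ex)
  mon <- matrix(0, n, m)
  dxi <- matrix(0, n, m)
  det_ <- matrix(0, n, m)
  for (l in seq_len(m)) {
    a <- ex[l, 1]; b <- ex[l, 2]
    mon[, l] <- pts[, 1]^a * pts[, 2]^b
    dxi[, l] <- if (a > 0) a * pts[, 1]^(a - 1) * pts[, 2]^b else 0
    det_[, l] <- if (b > 0) b * pts[, 1]^a * pts[, 2]^(b - 1) else 0
  }
  list(phi = t(mon %*% bc$C), dxi = t(dxi %*% bc$C), deta = t(det_ %*% bc$C))
}

# Symmetric Gauss rules on the reference triangle (weights sum to 1/2).
tri_quad <- function(degree) {
  perm3 <- function(a) rbind(c(a, a), c(1 - 2 * a, a), c(a, 1 - 2 * a))
  perm6 <- function(a, b) {
    c3 <- 1 - a - b
    rbind(c(a, b), c(b, a), c(a, c3), c(c3, a), c(b, c3), c(c3, b))
  }
  if (degree <= 1) {
    pts <- matrix(c(1 / 3, 1 / 3), 1, 2)
    w <- 1
  } else if (degree <= 2) {
    pts <- perm3(1 / 6)
    w <- rep(1 / 3, 3)
  } else if (degree <= 4) {
    pts <- rbind(perm3(0.445948490915965), perm3(0.091576213509771))
    w <- c(rep(0.223381589678011, 3), rep(0.109951743655322, 3))
  } else if (degree <= 6) {
    pts <- rbind(perm3(0.063089014491502), perm3(0.249286745170910),
                 perm6(0.310352451033785, 0.053145049844816))
    w <- c(rep(0.050844906370207, 3), rep(0.116786275726379, 3),
           rep(0.082851075618374, 6))
  } else {
    # degree 8, 16 points
    pts <- rbind(matrix(c(1 / 3, 1 / 3), 1, 2),
                 perm3(0.459292588292723),
                 perm3(0.170569307751760),
                 perm3(0.050547228317031),
                 perm6(0.263112829634638, 0.008394777409958))
    w <- c(0.144315607677787,
           rep(0.095091634413246, 3),
           rep(0.103217370534718, 3),
           rep(0.032458497623198, 3),
           rep(0.027230314174435, 6))
  }
  list(pts = pts, w = w / 2)
}

# basis tables (phi, dxi, deta, w) at a quadrature rule, for the kernels
tri_basis_table <- function(p, degree) {
  q <- tri_quad(degree)
  b <- tri_basis_eval(p, q$pts)
  list(phi = b$phi, dxi = b$dxi, deta = b$deta, w = q$w)
}

# quadrature degrees: full rule for the deviatoric part, reduced for the
# volumetric penalty (selective reduced integration against locking)
quad_degrees <- function(p) {
  switch(as.character(p),
         "1" = c(dev = 2, vol = 1),
         "2" = c(dev = 4, vol = 1),
         "3" = c(dev = 6, vol = 2),
         "4" = c(dev = 8, vol = 4),
         stop("unsupported element order: ", p))
}

# --- 1D edge bases (sequential lattice 0..p on [0,1]) -----------------------

gauss1d <- function(n) {
  if (n == 6) {
    a <- c(-0.932469514203152, -0.661209386466265, -0.238619186083197,
           0.238619186083197, 0.661209386466265, 0.932469514203152)
    wa <- c(0.171324492379170, 0.360761573048139, 0.467913934572691,
            0.467913934572691, 0.360761573048139, 0.171324492379170)
    return(list(x = (a + 1) / 2, w = wa / 2))
  }
  if (n == 2) {
    x <- 0.5 + c(-1, 1) / (2 * sqrt(3))
    w <- c(0.5, 0.5)
  } else if (n == 3) {
    x <- 0.5 + c(-1, 0, 1) * sqrt(3 / 5) / 2
    w <- c(5, 8, 5) / 18
  } else if (n == 5) {
    a <- c(-0.906179845938664, -0.538469310105683, 0,
           0.538469310105683, 0.906179845938664)
    wa <- c(0.236926885056189, 0.478628670499366, 0.568888888888889,
            0.478628670499366, 0.236926885056189)
    x <- (a + 1) / 2
    w <- wa / 2
  } else stop("gauss1d: unsupported n")
  list(x = x, w = w)
}

edge_basis_eval <- function(p, x) {
  nodes <- seq(0, 1, length.out = p + 1)
  V <- outer(nodes, 0:p, `^`)
  C <- solve(V)
  mon <- outer(x, 0:p, `^`)
  dmon <- outer(x, 0:p, function(xx, k) ifelse(k > 0, k * xx^pmax(k - 1, 0), 0))
  list(phi = t(mon %*% C), dphi = t(dmon %*% C))
}

edge_basis_table <- function(p, nq = max(3, p + 1)) {
  nq <- if (nq <= 2) 2 else if (nq <= 3) 3 else 5
  g <- gauss1d(nq)
  b <- edge_basis_eval(p, g$x)
  list(phi = b$phi, dphi = b$dphi, w = g$w)
}

# local lattice indices of the three element edges (CCW), order p
tri_edge_indices <- function(p) {
  idx <- function(i, j) {
    off <- 0L
    if (j > 0) off <- sum((p + 1) - 0:(j - 1))
    as.integer(off + i + 1)
  }
  bottom <- vapply(0:p, function(k) idx(k, 0), integer(1))
  hyp <- vapply(0:p, function(k) idx(p - k, k), integer(1))
  left <- vapply(0:p, function(k) idx(0, p - k), integer(1))
  cbind(bottom, hyp, left)
}

# exact edge rule for the boundary-integral element volume (degree 3p - 1)
tri_volume_edge_basis <- function(p) {
  nq <- if (p <= 2) 3 else 6
  g <- gauss1d(nq)
  b <- edge_basis_eval(p, g$x)
  list(phi = b$phi, dphi = b$dphi, w = g$w)
}

# monomial coefficients of the 1D edge basis: phi_i(s) = sum_j C[j+1, i] s^j
edge_basis_coeffs <- function(p) {
  nodes <- seq(0, 1, length.out = p + 1)
  V <- outer(nodes, 0:p, `^`)
  solve(V)
}
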