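#' Pratt algebraic circle fit
#'
#' Fits a circle `A (x^2 + y^2) + B x + C y + D = 0` to points by minimising
#' the algebraic distance under the Pratt normalisation
#' `B^2 + C^2 - 4 A D = 1`, which makes the fit exact for points on a circle
#' and nearly unbiased on partial arcs. Solved as the generalised eigenproblem
#' `M v = eta N v` on centred, scaled coordinates.
#'
#' @param points numeric matrix (n x 2) of coordinates, `n >= 3`.
#' @return list with `center` (length 2) and `radius`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' fit <- pratt_circle_fit(cbind(3 + 2 * cos(th), -1 + 2 * sin(th)))
#' fit$radius # 2
#' @export
pratt_circle_fit <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("pratt_circle_fit: need at least 3 points")
  ctr <- colMeans(points)
  x <- points[, 1] - ctr[1]
  y <- points[, 2] - ctr[2]
  s <- sqrt(mean(x^2 + y^2))
  if (s < .Machine$double.eps)
    stop("pratt_circle_fit: degenerate point set")
  x <- x / s
  y <- y / s
  z <- x^2 + y^2
  # collinearity check: smallest singular value of centred [x y]
  sv <- svd(cbind(x, y), nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * sv[1])
    stop("pratt_circle_fit: points are collinear (degenerate fit)")
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / nrow(Z)
  N <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(N, M))
  eta <- Re(ev$values)
  vec <- Re(ev$vectors)
  # admissible solutions satisfy v' N v > 0; take smallest non-negative eta
  ok <- which(eta > -1e-9)
  if (length(ok) == 0) stop("pratt_circle_fit: no admissible solution")
  k <- ok[which.min(eta[ok])]
  v <- vec[, k]
  nrm <- v[2]^2 + v[3]^2 - 4 * v[1] * v[4]
  if (nrm <= 0) stop("pratt_circle_fit: degenerate solution")
  v <- v / sqrt(nrm)
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]
  if (abs(A) < 1e-12)
    stop("pratt_circle_fit: points are collinear (degenerate fit)")
  cx <- -B / (2 * A)
  cy <- -C / (2 * A)
  r <- sqrt(B^2 + C^2 - 4 * A * D) / (2 * abs(A))
  list(center = c(cx * s + ctr[1], cy * s + ctr[2]), radius = r * s)
}
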