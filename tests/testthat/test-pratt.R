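# Pratt algebraic circle fit.

test_that("noiseless circles are recovered exactly", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  fit <- pratt_circle_fit(cbind(5 + 12.36 * cos(th), -3 + 12.36 * sin(th)))
  expect_equal(fit$radius, 12.36, tolerance = 1e-9)
  expect_equal(fit$center, c(5, -3), tolerance = 1e-9)
  # partial arc (the use case: posterior pole window)
  th <- seq(-0.3, 0.3, length.out = 50)
  fit <- pratt_circle_fit(cbind(13.36 * sin(th), 30.75 - 13.36 * cos(th)))
  expect_equal(fit$radius, 13.36, tolerance = 1e-8)
})

test_that("three points give the circumcircle", {
  set.seed(11)
  for (k in 1:5) {
    P <- matrix(rnorm(6, sd = 4), 3, 2)
    # closed-form circumcircle
    ax <- P[1, 1]; ay <- P[1, 2]; bx <- P[2, 1]; by <- P[2, 2]
    cx <- P[3, 1]; cy <- P[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-6) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r <- sqrt((ax - ux)^2 + (ay - uy)^2)
    fit <- pratt_circle_fit(P)
    expect_equal(fit$center, c(ux, uy), tolerance = 1e-6)
    expect_equal(fit$radius, r, tolerance = 1e-6)
  }
})

test_that("degenerate inputs raise errors", {
  expect_error(pratt_circle_fit(cbind(1:10, 2 * (1:10) + 3)), "collinear")
  expect_error(pratt_circle_fit(matrix(1, 2, 2)), "at least 3")
})

test_that("the fit is invariant under rigid translation", {
  th <- seq(0.2, 1.9, length.out = 30)
  pts <- cbind(7 * cos(th) + 0.01 * sin(9 * th), 7 * sin(th))
  f0 <- pratt_circle_fit(pts)
  f1 <- pratt_circle_fit(sweep(pts, 2, c(4.2, -8.8), "+"))
  expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
  expect_equal(f1$center, f0$center + c(4.2, -8.8), tolerance = 1e-7)
})
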