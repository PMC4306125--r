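test_that("affine parameters validate their domain", {
  expect_s3_class(affine_params(1, 0, 0, 0), "affine_params")
  expect_error(affine_params(0, 0, 0, 0), "k")
  expect_error(affine_params(-1, 0, 0, 0), "k")
  expect_error(affine_params(1, 4, 0, 0), "theta")
})

test_that("affine apply matches the hand-computed matrix product", {
  a <- affine_params(k = 2, theta = pi / 2, dx = 1, dy = -1)
  # k * [cos sin; -sin cos] %*% p + delta at p = (1, 0)
  expect_equal(as.numeric(affine_apply(a, c(1, 0))),
               c(2 * 0 + 1, 2 * (-1) - 1))
  # identity leaves points alone
  id <- affine_params(1, 0, 0, 0)
  p <- matrix(rnorm(20), 10, 2)
  expect_equal(affine_apply(id, p), p)
})

test_that("pure rotation preserves distances and scaling scales them", {
  p <- matrix(rnorm(40), 20, 2)
  rot <- affine_params(1, 0.7, 0, 0)
  q <- affine_apply(rot, p)
  expect_equal(as.numeric(dist(q)), as.numeric(dist(p)))
  sc <- affine_params(1.3, 0, 0, 0)
  expect_equal(as.numeric(dist(affine_apply(sc, p))),
               1.3 * as.numeric(dist(p)))
})

test_that("cubic B-spline basis matches closed forms and boundary values", {
  u <- seq(0, 1 - 1e-9, length.out = 101)
  expect_equal(bspline_basis(0, u), (1 - u)^3 / 6)
  expect_equal(bspline_basis(1, u), (3 * u^3 - 6 * u^2 + 4) / 6)
  expect_equal(bspline_basis(2, u), (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6)
  expect_equal(bspline_basis(3, u), u^3 / 6)
  expect_equal(bspline_basis(0, 0), 1 / 6)
  expect_equal(bspline_basis(3, 1 - 1e-12), 1 / 6, tolerance = 1e-9)
  expect_error(bspline_basis(4, 0.5), "m")
  expect_error(bspline_basis(0, 1.2), "u")
})

test_that("basis functions are non-negative and sum to one", {
  u <- runif(500)
  s <- bspline_basis(0, u) + bspline_basis(1, u) +
    bspline_basis(2, u) + bspline_basis(3, u)
  expect_lt(max(abs(s - 1)), 1e-12)
  for (m in 0:3) expect_true(all(bspline_basis(m, u) >= 0))
})

test_that("ffd grid validates lattice size and spacing", {
  expect_error(ffd_grid(array(0, c(3, 4, 2)), 8, c(0, 0)), "4")
  expect_error(ffd_grid(array(0, c(4, 4, 2)), c(0, 8), c(0, 0)), "delta|spacing")
  g <- default_ffd_grid(c(64, 64), 8)
  expect_s3_class(g, "ffd_grid")
  expect_equal(g$origin, c(-8, -8))
})

test_that("zero lattice gives zero displacement everywhere", {
  g <- default_ffd_grid(c(32, 48), 8)
  p <- cbind(runif(50, 0, 47), runif(50, 0, 31))
  expect_equal(ffd_displacement(g, p), matrix(0, 50, 2))
})

test_that("uniformly shifted lattice translates by the shift", {
  # partition of unity: constant control displacements reproduce exactly
  g <- default_ffd_grid(c(32, 32), 8)
  g$phi[, , 1] <- 1.25
  g$phi[, , 2] <- -0.5
  p <- cbind(runif(50, 0, 31), runif(50, 0, 31))
  d <- ffd_displacement(g, p)
  expect_equal(d[, 1], rep(1.25, 50), tolerance = 1e-12)
  expect_equal(d[, 2], rep(-0.5, 50), tolerance = 1e-12)
})

test_that("ffd displacement matches the 16-term brute-force sum", {
  set.seed(42)
  g <- default_ffd_grid(c(48, 48), 8)
  g$phi <- array(rnorm(prod(dim(g$phi))), dim = dim(g$phi))
  p <- cbind(runif(100, 0, 47), runif(100, 0, 47))
  oracle <- t(apply(p, 1, function(pt) {
    s <- (pt - g$origin) / g$delta
    i0 <- floor(s[1]) - 1; j0 <- floor(s[2]) - 1
    u <- s[1] - floor(s[1]); v <- s[2] - floor(s[2])
    out <- c(0, 0)
    for (m in 0:3) for (n in 0:3) {
      w <- bspline_basis(m, u) * bspline_basis(n, v)
      out <- out + w * g$phi[i0 + m + 1, j0 + n + 1, ]
    }
    out
  }))
  expect_lt(max(abs(ffd_displacement(g, p) - oracle)), 1e-10)
})

test_that("points outside the lattice support are rejected", {
  g <- ffd_grid(array(0, c(4, 4, 2)), delta = 8, origin = c(0, 0))
  expect_silent(ffd_displacement(g, cbind(8.5, 8.5)))
  expect_error(ffd_displacement(g, cbind(100, 8)), "support")
})

test_that("hierarchical transform is the sum of its displacements", {
  a <- affine_params(1.05, 0.1, 2, -1)
  g <- default_ffd_grid(c(32, 32), 8)
  set.seed(7)
  g$phi <- array(rnorm(prod(dim(g$phi)), sd = 0.5), dim = dim(g$phi))
  tr <- hierarchical_transform(a, g)
  p <- cbind(runif(20, 0, 31), runif(20, 0, 31))
  expect_equal(combined_apply(tr, p),
               p + global_displacement(a, p) + ffd_displacement(g, p))
})

test_that("transforms round-trip through JSON text", {
  a <- affine_params(1.05, -0.2, 3.5, 0.25)
  g <- default_ffd_grid(c(32, 32), 8)
  g$phi <- array(seq_len(prod(dim(g$phi))) * 0.01, dim = dim(g$phi))
  tr <- hierarchical_transform(a, g)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  transform_to_json(tr, f)
  tr2 <- transform_from_json(f)
  p <- cbind(runif(10, 0, 31), runif(10, 0, 31))
  expect_equal(combined_apply(tr2, p), combined_apply(tr, p),
               tolerance = 1e-12)
})
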