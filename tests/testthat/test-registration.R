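test_that("optimizer config validates gain and tolerance", {
  expect_s3_class(optimizer_config(), "optimizer_config")
  expect_error(optimizer_config(gain = 0), "gain")
  expect_error(optimizer_config(tolerance = -1), "tolerance")
})

test_that("gradient descent minimizes a quadratic bowl", {
  fn <- function(mu) sum((mu - c(3, -2))^2)
  fit <- gradient_descent(fn, c(0, 0),
                          optimizer_config(max_iterations = 500,
                                           step0 = 0.5, tolerance = 1e-14))
  expect_equal(fit$mu, c(3, -2), tolerance = 1e-4)
  expect_true(all(diff(fit$trajectory$cost) <= 0))  # accepted steps only
  expect_error(gradient_descent(function(mu) NaN, 0), "finite")
})

test_that("spline resampling is exact at pixel centers and for linears", {
  set.seed(3)
  img <- matrix(rnorm(30 * 40), 30, 40)
  co <- lvstrain:::pixel_grid(dim(img))
  expect_lt(max(abs(resample(img, co) - img)), 1e-8)
  # cubic spline interpolation reproduces an affine intensity surface
  lin <- outer(1:30, 1:40, function(r, c) 0.3 * r - 0.1 * c + 2)
  # interior only: the mirror boundary condition kinks a linear surface
  half <- list(x = co$x[6:24, 6:34] + 0.5, y = co$y[6:24, 6:34] + 0.25)
  vals <- resample(lin, half)
  want <- 0.3 * (half$y + 1) - 0.1 * (half$x + 1) + 2
  expect_lt(max(abs(vals - want)), 1e-3)
})

test_that("out-of-image samples are clamped and flagged in the mask", {
  img <- matrix(1:20, 4, 5)
  v <- resample(img, list(x = c(-3, 2), y = c(1, 100)))
  expect_equal(attr(v, "mask"), c(FALSE, FALSE))
  v2 <- resample(img, list(x = 2, y = 1))
  expect_true(attr(v2, "mask"))
})

test_that("warp coordinates of a pure translation shift the grid", {
  a <- affine_params(1, 0, 2.5, -1)
  co <- warp_coords(a, c(8, 10))
  g <- lvstrain:::pixel_grid(c(8, 10))
  expect_equal(co$x, g$x + 2.5)
  expect_equal(co$y, g$y - 1)
})

test_that("gaussian smoothing preserves constants and reduces noise", {
  expect_equal(smooth_image(matrix(0.7, 16, 16), 1.5), matrix(0.7, 16, 16))
  set.seed(8)
  noisy <- matrix(rnorm(64 * 64), 64, 64)
  sm <- smooth_image(noisy, 1)
  expect_lt(stats::var(as.numeric(sm)), 0.25 * stats::var(as.numeric(noisy)))
  expect_identical(smooth_image(noisy, 0), noisy)
})

test_that("global stage recovers a small translation on the phantom", {
  spec <- phantom_spec(size = 64, r_endo = 10, r_epi = 18, noise_sd = 0.01)
  ref <- phantom_affine_frame(spec, affine_params(1, 0, 0, 0), seed = 2)
  a_true <- affine_params(1, 0, 1.5, -1)
  tgt <- phantom_affine_frame(spec, a_true, seed = 3)
  fit <- register_global(ref, tgt,
                         optimizer_config(step0 = c(0.002, 0.002, 0.25, 0.25),
                                          gradient_step = c(0.005, 0.005, 0.01, 0.01),
                                          max_iterations = 100))
  expect_equal(fit$dx, 1.5, tolerance = 0.1)
  expect_equal(fit$dy, -1, tolerance = 0.1)
  expect_equal(fit$k, 1, tolerance = 0.005)
  expect_error(register_global(ref, matrix(0, 4, 4)), "identical shapes")
})

test_that("local stage cost trajectory is monotone non-increasing", {
  ph <- small_phantom(seed = 2)
  ref <- ph$cine$frames[[1]]
  tgt <- ph$cine$frames[[3]]
  aff <- register_global(ref, tgt)
  res <- register_local(ref, tgt, aff,
                        config = optimizer_config(max_iterations = 25),
                        cost_config = cost_config(lambda = 0))
  traj <- attr(res, "trajectory")
  expect_true(all(diff(traj$total) <= 0))
  expect_equal(traj$c_icp, rep(0, nrow(traj)))
  expect_lt(traj$total[nrow(traj)], traj$total[1])
})

test_that("contour term enters the local stage objective and decreases", {
  ph <- small_phantom(seed = 2)
  spec <- ph$truth$spec
  ref <- ph$cine$frames[[1]]
  tgt <- ph$cine$frames[[4]]
  aff <- affine_params(1, 0, 0, 0)
  res <- register_local(ref, tgt, aff,
                        contours_ref = ph$truth$contours[["0"]],
                        contours_target = ph$truth$contours[["3"]],
                        config = optimizer_config(max_iterations = 40),
                        cost_config = cost_config(lambda = 1),
                        grid_spacing = 8)
  traj <- attr(res, "trajectory")
  expect_gt(traj$c_icp[1], 0)
  expect_true(is.numeric(attr(res, "warm_iterations")))
  expect_true(all(diff(traj$total) <= 1e-12))
})

test_that("displacement field of a translation is constant", {
  tr <- hierarchical_transform(affine_params(1, 0, 0.75, -0.25),
                               default_ffd_grid(c(16, 16), 8))
  f <- displacement_field(tr, c(16, 16), frame = 2L)
  expect_s3_class(f, "displacement_field")
  expect_equal(unique(as.numeric(f$u[, , 1])), 0.75)
  expect_equal(unique(as.numeric(f$u[, , 2])), -0.25)
  f0 <- displacement_field(NULL, c(16, 16))
  expect_equal(max(abs(f0$u)), 0)
})

test_that("sequence extraction returns one field per frame, frame 0 zero", {
  ph <- small_phantom(seed = 4)
  cfg <- optimizer_config(max_iterations = 15)
  seq_res <- extract_displacement_sequence(
    ph$cine, cost_config = cost_config(lambda = 0),
    global_config = optimizer_config(max_iterations = 20,
                                     step0 = c(0.002, 0.002, 0.25, 0.25),
                                     gradient_step = c(0.005, 0.005, 0.01, 0.01)),
    local_config = cfg)
  expect_s3_class(seq_res, "displacement_sequence")
  expect_length(seq_res$fields, 8L)
  expect_equal(max(abs(seq_res$fields[[1]]$u)), 0)
  expect_length(seq_res$failures, 0L)
  expect_null(seq_res$transforms[[1]])
  expect_s3_class(seq_res$transforms[[2]], "hierarchical_transform")
})
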