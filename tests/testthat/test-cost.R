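test_that("cost configuration validates weights", {
  expect_s3_class(cost_config(), "cost_config")
  expect_error(cost_config(lambda = -1), "lambda")
  expect_error(cost_config(alpha1 = -0.1), "alpha1")
  expect_error(cost_config(alpha2 = -2), "alpha2")
})

test_that("ssd is the mean squared difference and is zero on identity", {
  a <- matrix(runif(100), 10, 10)
  expect_equal(ssd(a, a), 0)
  b <- a + 0.5
  expect_equal(ssd(a, b), 0.25)
  expect_error(ssd(a, matrix(0, 5, 5)), "shape")
})

test_that("feature distance is the weighted squared position + curvature gap", {
  m1 <- c(1, 2, 0.10)
  m2 <- c(4, 6, 0.12)
  expect_equal(feature_distance(m1, m2, 2, 100),
               2 * (9 + 16) + 100 * 0.02^2)
  expect_equal(feature_distance(m1, m1, 2, 100), 0)
  expect_error(feature_distance(m1, m2, -1, 0), "alpha1")
})

test_that("alpha weights are reciprocal pairwise ranges", {
  # two distinct circles: positional range is informative, curvature range
  # across the pair of radii is informative too if radii differ enough
  s <- contour_point_set(circle_points(10, c(30, 30)), "s")
  t <- contour_point_set(circle_points(20, c(30, 30)), "t")
  a <- suppressWarnings(compute_alpha_weights(s, t))
  d2 <- outer(t$points[, 1], s$points[, 1], "-")^2 +
    outer(t$points[, 2], s$points[, 2], "-")^2
  expect_equal(unname(a["alpha1"]), 1 / (max(d2) - min(d2)))
})

test_that("degenerate curvature range gets zero weight with a warning", {
  # concentric circles sampled identically: all pairwise curvature
  # differences are (numerically) equal, so curvature cannot discriminate
  s <- contour_point_set(circle_points(10, c(30, 30)), "s")
  t <- contour_point_set(circle_points(10.01, c(30, 30)), "t")
  expect_warning(a <- compute_alpha_weights(s, t), "curvature")
  expect_equal(unname(a["alpha2"]), 0)
  expect_gt(a["alpha1"], 0)
})

test_that("matching recovers an index shift between identical contours", {
  p <- circle_points(12, c(20, 20), n = 32)
  s <- contour_point_set(p, "s")
  shifted <- contour_point_set(p[c(4:32, 1:3), ], "t")
  m <- icpif_match(s, shifted, alpha1 = 1, alpha2 = 0)
  expect_s3_class(m, "correspondence_set")
  expect_equal(m$match_index, c(4:32, 1:3))
  expect_equal(max(m$distances), 0)
})

test_that("curvature feature breaks positional ties", {
  # two source points equidistant from the probe; curvature selects one
  src <- contour_point_set(circle_points(10, c(0, 0), n = 16), "s",
                           curvatures = c(0.5, rep(0.1, 15)))
  probe <- contour_point_set(circle_points(10, c(0, 0), n = 16), "t",
                             curvatures = rep(0.5, 16))
  m0 <- icpif_match(src, probe, alpha1 = 1, alpha2 = 0)
  mk <- icpif_match(src, probe, alpha1 = 0, alpha2 = 1)
  expect_equal(m0$match_index, 1:16)      # pure position: identity
  expect_equal(unique(mk$match_index), 1L) # pure curvature: all pick point 1
})

test_that("correspondence penalty is a sum, not a mean", {
  # concentric circles sampled at the same phases: every moving point's
  # closest source point is the same-angle point at radial distance 2, so
  # the penalty is exactly n * alpha1 * 2^2 and doubles with the sampling
  pen <- function(n) {
    s <- contour_point_set(circle_points(10, c(0, 0), n = n), "s")
    t <- contour_point_set(circle_points(12, c(0, 0), n = n), "t",
                           curvatures = s$curvatures)
    c_icp(icpif_match(s, t, alpha1 = 1, alpha2 = 0))
  }
  expect_equal(pen(16), 16 * 4, tolerance = 1e-12)
  expect_equal(pen(32), 2 * pen(16), tolerance = 1e-12)
})

test_that("total cost reduces to ssd without contours and is zero at self", {
  ph <- small_phantom()
  ref <- ph$cine$frames[[1]]
  id <- hierarchical_transform(affine_params(1, 0, 0, 0),
                               default_ffd_grid(dim(ref), 8))
  v <- total_cost(ref, ref, id, config = cost_config(lambda = 0))
  expect_lt(as.numeric(v), 1e-16)
  expect_equal(attr(v, "c_icp"), 0)
  expect_equal(attr(v, "c_sim"), as.numeric(v))
})

test_that("total cost adds lambda times the contour penalty", {
  ph <- small_phantom()
  ref <- ph$cine$frames[[1]]
  tgt <- ph$cine$frames[[4]]
  id <- hierarchical_transform(affine_params(1, 0, 0, 0),
                               default_ffd_grid(dim(ref), 8))
  cr <- ph$truth$contours[["0"]]
  ct <- ph$truth$contours[["3"]]
  v0 <- total_cost(ref, tgt, id, cr, ct, cost_config(lambda = 0))
  v1 <- total_cost(ref, tgt, id, cr, ct, cost_config(lambda = 1))
  v2 <- total_cost(ref, tgt, id, cr, ct, cost_config(lambda = 2))
  expect_equal(attr(v1, "c_sim"), attr(v0, "c_sim"))
  expect_gt(attr(v1, "c_icp"), 0)
  expect_equal(as.numeric(v2) - as.numeric(v1), attr(v1, "c_icp"),
               tolerance = 1e-10)
})
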