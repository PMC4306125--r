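coord_mats <- function(nr, nc) {
  list(x = matrix(rep(0:(nc - 1), each = nr), nr, nc),
       y = matrix(rep(0:(nr - 1), times = nc), nr, nc))
}

linear_field <- function(nr, nc, fun) {
  g <- coord_mats(nr, nc)
  u <- array(0, c(nr, nc, 2))
  d <- fun(g$x, g$y)
  u[, , 1] <- d$ux; u[, , 2] <- d$uy
  u
}

test_that("deformation gradient of a linear field is exact", {
  u <- linear_field(20, 24, function(x, y)
    list(ux = 0.1 * x + 0.03 * y, uy = -0.02 * x + 0.05 * y))
  f <- deformation_gradient(u)
  expect_equal(max(abs(f[, , 1, 1] - 1.1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f[, , 1, 2] - 0.03)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f[, , 2, 1] + 0.02)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f[, , 2, 2] - 1.05)), 0, tolerance = 1e-12)
})

test_that("anisotropic pixel spacing enters the gradient as a ratio", {
  # pure shear in pixels; with spacing (2, 1) mm the physical dux/dy halves
  u <- linear_field(16, 16, function(x, y) list(ux = 0.1 * y, uy = 0 * x))
  f <- deformation_gradient(u, spacing = c(2, 1))
  expect_equal(f[8, 8, 1, 2], 2 / 1 * 0.1)
  f2 <- deformation_gradient(u, spacing = c(1, 2))
  expect_equal(f2[8, 8, 1, 2], 1 / 2 * 0.1)
})

test_that("green strain of a uniform scaling matches the closed form", {
  s <- 1.1
  u <- linear_field(30, 30, function(x, y)
    list(ux = (s - 1) * (x - 14.5), uy = (s - 1) * (y - 14.5)))
  E <- strain_tensor(deformation_gradient(u))
  expect_equal(E$E_xx[10, 10], (s^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(E$E_yy[20, 5], (s^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(max(abs(E$E_xy)), 0, tolerance = 1e-12)
})

test_that("green strain vanishes identically under rigid rotation", {
  th <- 0.3
  u <- linear_field(25, 25, function(x, y) {
    xc <- x - 12; yc <- y - 12
    list(ux = cos(th) * xc - sin(th) * yc - xc,
         uy = sin(th) * xc + cos(th) * yc - yc)
  })
  E <- strain_tensor(deformation_gradient(u))
  expect_lt(max(abs(E$E_xx)), 1e-12)
  expect_lt(max(abs(E$E_xy)), 1e-12)
  expect_lt(max(abs(E$E_yy)), 1e-12)
})

test_that("radial and circumferential projections agree with isotropy", {
  s <- 1.1
  cenp <- c(15, 15)
  u <- linear_field(31, 31, function(x, y)
    list(ux = (s - 1) * (x - cenp[1]), uy = (s - 1) * (y - cenp[2])))
  pr <- radial_strain(strain_tensor(deformation_gradient(u)), cenp)
  want <- 100 * (s^2 - 1) / 2
  expect_equal(pr$radial_pct[5, 20], want, tolerance = 1e-9)
  expect_equal(pr$circ_pct[25, 8], want, tolerance = 1e-9)
  # engineering reading: sqrt(s^2) - 1 = 10%
  expect_equal(pr$radial_eng_pct[5, 20], 100 * (s - 1), tolerance = 1e-9)
  expect_true(is.na(pr$radial_pct[16, 16]))  # centroid pixel undefined
})

test_that("strain rate differentiates a linear ramp exactly", {
  e <- seq(0, 0.14, length.out = 8)       # fractional strain per frame
  sr <- strain_rate(e, frame_interval = 50)
  expect_equal(sr, rep(0.02 / 0.05, 8))   # 0.02 per 50 ms = 0.4 / s
  m <- cbind(e, 2 * e)
  expect_equal(strain_rate(m, 50)[, 2], rep(0.8, 8), ignore_attr = TRUE)
  expect_error(strain_rate(e[1:2], 50), "3 frames")
  expect_error(strain_rate(e, c(50, 60, 50, 50, 50, 50, 50, 50)),
               "uniform")
})

test_that("myocardium mask is the annulus between the contours", {
  endo <- circle_points(8, c(24, 24), n = 128)
  epi <- circle_points(15, c(24, 24), n = 128)
  m <- myocardium_mask(endo, epi, c(48, 48))
  expect_equal(sum(m), pi * (15^2 - 8^2), tolerance = 0.03)
  # a point clearly in the cavity and one outside are excluded
  expect_false(m[25, 25])
  expect_false(m[2, 2])
  expect_true(m[25, 24 + 12])  # (x = 35, y = 24) mid-wall
})

test_that("contour centroid recovers a circle center", {
  expect_equal(contour_centroid(circle_points(11, c(30.5, 20.25), n = 64)),
               c(30.5, 20.25), ignore_attr = TRUE)
})

test_that("aha model partitions the mask into the level's sectors", {
  endo <- circle_points(8, c(32, 32), n = 128)
  epi <- circle_points(15, c(32, 32), n = 128)
  mask <- myocardium_mask(endo, epi, c(64, 64))
  for (lv in c("basal", "mid", "apical")) {
    sm <- aha_segments(mask, c(32, 32), rv_insertion_angle = pi / 3,
                       level = lv)
    ids <- switch(lv, basal = 1:6, mid = 7:12, apical = 13:16)
    expect_equal(sm$segment_ids, ids)
    expect_setequal(unique(sm$labels[mask]), ids)
    expect_true(all(sm$labels[!mask] == 0L))    # disjoint, union = mask
    cnt <- table(sm$labels[mask])
    expect_lt(diff(range(cnt)) / mean(cnt), 0.1) # near-equal sectors
  }
  expect_error(aha_segments(mask, c(5, 5)), "empty")
})

test_that("rotating the rv insertion angle permutes the sector labels", {
  endo <- circle_points(8, c(32, 32), n = 128)
  epi <- circle_points(15, c(32, 32), n = 128)
  mask <- myocardium_mask(endo, epi, c(64, 64))
  a <- aha_segments(mask, c(32, 32), 0, "mid")
  b <- aha_segments(mask, c(32, 32), 2 * pi / 6, "mid")
  # rotating by one sector width shifts each label by one (cyclically)
  sel <- mask & a$labels > 0 & b$labels > 0
  shift <- (a$labels[sel] - 7L - (b$labels[sel] - 7L)) %% 6L
  expect_true(mean(shift == 1L) > 0.95)  # boundary pixels may straddle
})

test_that("global segment curve is the area-weighted mean of the segments", {
  endo <- circle_points(8, c(24, 24), n = 128)
  epi <- circle_points(15, c(24, 24), n = 128)
  mask <- myocardium_mask(endo, epi, c(48, 48))
  model <- aha_segments(mask, c(24, 24), 0, "mid")
  s_of_t <- c(1, 1.04, 1.08, 1.1)
  fields <- lapply(s_of_t, function(s)
    linear_field(48, 48, function(x, y)
      list(ux = (s - 1) * (x - 24), uy = (s - 1) * (y - 24))))
  cur <- segment_curves(fields, model, spacing = c(1, 1),
                        frame_interval = 40)
  expect_s3_class(cur, "tbl_df")
  expect_setequal(unique(cur$segment_id), c(0L, 7:12))
  glob <- cur[cur$segment_id == 0L, ]
  segs <- cur[cur$segment_id > 0L, ]
  cnt <- as.numeric(table(model$labels[mask]))
  for (t in unique(segs$frame)) {
    sv <- segs$radial_strain_pct[segs$frame == t]
    expect_equal(glob$radial_strain_pct[glob$frame == t],
                 sum(sv * cnt) / sum(cnt), tolerance = 1e-9)
  }
  # uniform scaling: all segments carry the same strain
  expect_lt(diff(range(segs$radial_strain_pct[segs$frame == 3L])), 1e-6)
  expect_equal(glob$radial_strain_pct[glob$frame == 3L],
               100 * (1.1^2 - 1) / 2, tolerance = 1e-6)
})
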