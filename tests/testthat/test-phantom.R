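test_that("phantom spec validates its geometry and cycle", {
  expect_error(phantom_spec(size = 64, r_endo = 20, r_epi = 18), "r_endo")
  expect_error(phantom_spec(size = 40, r_endo = 10, r_epi = 25), "r_endo")
  expect_error(phantom_spec(frames = 4), "8 frames")
  expect_error(phantom_spec(contraction = 1), "contraction")
})

test_that("activation is 0 at end-diastole, 1 at peak, 0 at cycle end", {
  spec <- phantom_spec(frames = 12, systole_fraction = 1 / 3)
  expect_equal(phantom_activation(spec, 0), 0)
  expect_equal(phantom_activation(spec, 4), 1)    # 12 * 1/3
  expect_equal(phantom_activation(spec, 12), 0, tolerance = 1e-12)
  a <- phantom_activation(spec, 0:12)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("the programmed deformation is exactly invertible", {
  spec <- phantom_spec(size = 64, r_endo = 10, r_epi = 18,
                       twist_deg = 6, rotation_deg = 2, noise_sd = 0)
  set.seed(5)
  th <- runif(40, -pi, pi)
  rr <- runif(40, 2, 28)
  cen <- c(31.5, 31.5)
  p <- cbind(cen[1] + rr * cos(th), cen[2] + rr * sin(th))
  for (t in c(3, 7)) {
    moved <- p + phantom_displacement(spec, t, p)
    inv <- lvstrain:::phantom_inverse_polar(spec, t, moved[, 1], moved[, 2])
    back <- cbind(cen[1] + inv$r * cos(inv$beta),
                  cen[2] + inv$r * sin(inv$beta))
    expect_lt(max(abs(back - p)), 1e-8)
  }
})

test_that("peak-systole endocardial radius matches the contraction setting", {
  spec <- phantom_spec(size = 64, r_endo = 10, r_epi = 18,
                       contraction = 0.25, frames = 12,
                       systole_fraction = 1 / 3, noise_sd = 0)
  cen <- c(31.5, 31.5)
  p <- cbind(cen[1] + 10, cen[2])       # a point on the endocardium
  moved <- p + phantom_displacement(spec, 4, p)  # activation = 1
  expect_equal(sqrt(sum((moved - cen)^2)), 10 * 0.75, tolerance = 1e-10)
})

test_that("ground-truth contours are the advected reference contours", {
  ph <- small_phantom()
  spec <- ph$truth$spec
  e0 <- ph$truth$contours[["0"]]$endo$points
  e3 <- ph$truth$contours[["3"]]$endo$points
  expect_equal(e3, e0 + phantom_displacement(spec, 3, e0), tolerance = 1e-12)
})

test_that("phantom generation is deterministic in the seed", {
  a <- small_phantom(seed = 9)
  b <- small_phantom(seed = 9)
  c <- small_phantom(seed = 10)
  expect_identical(a$cine$frames, b$cine$frames)
  expect_false(identical(a$cine$frames[[2]], c$cine$frames[[2]]))
  # noise-free parts (truth) are seed-independent
  expect_equal(a$truth$contours, c$truth$contours)
})

test_that("weak-edge variant erases the epicardial step only in the arc", {
  base <- phantom_spec(size = 96, noise_sd = 0)
  weak <- weak_edge_variant(base, center_deg = -90, width_deg = 70,
                            reduction = 1)
  cen <- c(47.5, 47.5)
  r <- base$r_epi
  # intensity step across the epicardium, at the arc center vs opposite
  step_at <- function(spec, beta) {
    lo <- lvstrain:::phantom_intensity(spec, r - 3, beta)
    hi <- lvstrain:::phantom_intensity(spec, r + 3, beta)
    abs(hi - lo)
  }
  expect_lt(step_at(weak, -pi / 2), 0.25 * step_at(base, -pi / 2))
  expect_equal(step_at(weak, pi / 2), step_at(base, pi / 2))
  expect_error(weak_edge_variant(base, reduction = 2), "reduction")
})

test_that("analytic radial strain matches differentiating the truth", {
  spec <- phantom_spec(size = 64, r_endo = 10, r_epi = 18,
                       twist_deg = 8, noise_sd = 0)
  cen <- c(31.5, 31.5)
  t <- 5
  th <- pi / 3
  rr <- seq(11, 17, by = 1.5)
  p <- cbind(cen[1] + rr * cos(th), cen[2] + rr * sin(th))
  e <- analytic_radial_strain(spec, t, p)
  # numerical derivative of the forward map along the radial fiber
  h <- 1e-4
  ph1 <- p + phantom_displacement(spec, t, p)
  p2 <- cbind(cen[1] + (rr + h) * cos(th), cen[2] + (rr + h) * sin(th))
  ph2 <- p2 + phantom_displacement(spec, t, p2)
  stretch2 <- rowSums((ph2 - ph1)^2) / h^2
  expect_equal(e, (stretch2 - 1) / 2, tolerance = 1e-5)
  # outside the annulus the analytic strain is NA
  expect_true(is.na(analytic_radial_strain(spec, t, cbind(cen[1] + 5, cen[2]))))
})

test_that("rendered frame intensity moves with the stated field", {
  # noise-free phantom: frame t sampled at reference position p equals the
  # reference intensity at the material point that lands on p
  spec <- phantom_spec(size = 64, r_endo = 10, r_epi = 18, noise_sd = 0,
                       texture_amplitude = 0.2)
  ph <- phantom_generate(spec)
  ref <- ph$cine$frames[[1]]
  tgt <- ph$cine$frames[[5]]
  # pick a mid-wall material point and follow it
  cen <- ph$truth$centroid
  p <- cbind(cen[1] + 14 * cos(0.9), cen[2] + 14 * sin(0.9))
  moved <- p + phantom_displacement(spec, 4, p)
  val_ref <- lvstrain:::bilinear_interp(ref, p[, 1], p[, 2])
  val_tgt <- lvstrain:::bilinear_interp(tgt, moved[, 1], moved[, 2])
  expect_equal(val_ref, val_tgt, tolerance = 0.02)
})
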