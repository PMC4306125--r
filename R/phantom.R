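#' Specification of the beating-annulus phantom
#'
#' A synthetic short-axis left ventricle: a bright myocardial annulus
#' around a mid-gray blood pool on a dark background, contracting and
#' thickening over one cardiac cycle with an analytically known
#' deformation. The radial map linearly interpolates squared radii between
#' identity and the peak-systolic configuration, so it is exactly
#' invertible and monotone; an optional rigid rotation, linear-in-radius
#' twist, hypokinetic sector (locally scaled contraction) and weak-edge arc
#' (locally reduced epicardial contrast) emulate the failure modes the
#' contour-constrained registration is designed for.
#'
#' @param size image side length in pixels.
#' @param r_endo,r_epi end-diastolic endo/epicardial radii in pixels
#'   (0 < r_endo < r_epi < size/2).
#' @param contraction peak endocardial inward displacement as a fraction of
#'   `r_endo`.
#' @param thickening peak wall-thickening fraction (relative thickness
#'   change at peak systole).
#' @param rotation_deg rigid rotation amplitude (degrees at peak).
#' @param twist_deg twist amplitude: rotation at `r_epi`, scaling linearly
#'   with radius (degrees at peak).
#' @param frames frames per cycle (>= 8); frame 0 is end-diastole.
#' @param systole_fraction fraction of the cycle spent in systolic
#'   contraction; the activation rises as a raised cosine over it and
#'   recovers more slowly over the remainder, returning to 0 at cycle end.
#' @param intensity named levels `c(cavity, myo, background)` in [0, 1].
#' @param texture_amplitude relative amplitude of the smooth intramural
#'   intensity texture that gives the registration something to grip.
#' @param noise_sd additive Gaussian intensity noise standard deviation.
#' @param seed RNG seed for the noise.
#' @param pixel_spacing in-plane pixel size in mm (metadata).
#' @param frame_interval frame interval in ms (metadata).
#' @param hypokinetic optional `list(center_deg, width_deg, scale)`: within
#'   the sector the contraction amplitude is multiplied by `scale` (< 1),
#'   with smooth angular tapering.
#' @param weak_edge optional `list(center_deg, width_deg, reduction)`:
#'   within the arc the background level is raised toward the myocardial
#'   level by `reduction` in [0, 1], weakening the epicardial edge.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 96L, r_endo = 14, r_epi = 26,
                         contraction = 0.2, thickening = 0.15,
                         rotation_deg = 0, twist_deg = 0,
                         frames = 20L, systole_fraction = 1 / 3,
                         intensity = c(cavity = 0.5, myo = 0.9,
                                       background = 0.15),
                         texture_amplitude = 0.15,
                         noise_sd = 0.02, seed = 1L,
                         pixel_spacing = 1.25, frame_interval = 40,
                         hypokinetic = NULL, weak_edge = NULL) {
  if (!(r_endo > 0 && r_epi > r_endo && r_epi < size / 2))
    stop("need 0 < r_endo < r_epi < size/2")
  if (frames < 8L) stop("need at least 8 frames per cycle")
  if (contraction < 0 || contraction >= 1)
    stop("'contraction' must be in [0, 1)")
  rho_i <- r_endo * (1 - contraction)
  rho_o <- rho_i + (1 + thickening) * (r_epi - r_endo)
  if (rho_i <= 0 || rho_o <= rho_i)
    stop("contraction/thickening leave non-positive radii")
  if (!is.null(weak_edge) && (weak_edge$reduction < 0 || weak_edge$reduction > 1))
    stop("'weak_edge$reduction' must be in [0, 1]")
  structure(list(size = as.integer(size), r_endo = r_endo, r_epi = r_epi,
                 contraction = contraction, thickening = thickening,
                 rotation_deg = rotation_deg, twist_deg = twist_deg,
                 frames = as.integer(frames),
                 systole_fraction = systole_fraction,
                 intensity = intensity,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 pixel_spacing = pixel_spacing,
                 frame_interval = frame_interval,
                 hypokinetic = hypokinetic, weak_edge = weak_edge),
            class = "phantom_spec")
}

#' Activation profile of the phantom cycle
#'
#' Raised-cosine systolic rise over the first `systole_fraction` of the
#' cycle, slower cosine diastolic recovery over the rest; 0 at frame 0 and
#' again at frame `frames` (cyclic).
#'
#' @param spec a [phantom_spec()].
#' @param frame frame index (0-based), vectorized.
#' @return Activation in [0, 1].
#' @export
phantom_activation <- function(spec, frame) {
  p <- frame / spec$frames
  ps <- spec$systole_fraction
  ifelse(p <= ps,
         0.5 * (1 - cos(pi * p / ps)),
         0.5 * (1 + cos(pi * (p - ps) / (1 - ps))))
}

phantom_center <- function(spec) c(spec$size - 1, spec$size - 1) / 2

# peak-systole radial-map coefficients: rho^2 = b r^2 - a in the annulus
phantom_peak_coefs <- function(spec) {
  ri <- spec$r_endo; ro <- spec$r_epi
  rho_i <- ri * (1 - spec$contraction)
  rho_o <- rho_i + (1 + spec$thickening) * (ro - ri)
  b <- (rho_o^2 - rho_i^2) / (ro^2 - ri^2)
  a <- b * ri^2 - rho_i^2
  list(a = a, b = b)
}

# smooth angular window, 1 inside the arc, cosine-tapered edges (taper_deg)
angular_window <- function(beta, center_deg, width_deg, taper_deg = 10) {
  d <- abs(((beta - center_deg * pi / 180 + pi) %% (2 * pi)) - pi)
  half <- width_deg * pi / 360
  tap <- taper_deg * pi / 180
  w <- numeric(length(d))
  w[d <= half] <- 1
  edge <- d > half & d < half + tap
  w[edge] <- 0.5 * (1 + cos(pi * (d[edge] - half) / tap))
  w
}

# local motion scale as a function of material angle
phantom_motion_scale <- function(spec, beta) {
  if (is.null(spec$hypokinetic)) return(rep(1, length(beta)))
  h <- spec$hypokinetic
  1 - (1 - h$scale) * angular_window(beta, h$center_deg, h$width_deg)
}

# forward radial map rho(r) at effective activation A (vectorized over r, A)
phantom_radial_map <- function(spec, r, A) {
  pc <- phantom_peak_coefs(spec)
  ri <- spec$r_endo; ro <- spec$r_epi
  rmax <- spec$size / 2
  A <- rep_len(A, length(r))
  at <- A * pc$a; bt <- 1 + A * (pc$b - 1)
  rho_i <- sqrt(bt * ri^2 - at)
  rho_o <- sqrt(bt * ro^2 - at)
  out <- r
  inr <- r <= ri
  out[inr] <- r[inr] * (rho_i[inr] / ri)
  ann <- r > ri & r <= ro
  out[ann] <- sqrt(bt[ann] * r[ann]^2 - at[ann])
  ext <- r > ro & r < rmax
  out[ext] <- r[ext] + (rho_o[ext] - ro) *
    ((rmax - r[ext]) / (rmax - ro))^2
  out
}

# inverse of the radial map (vectorized); exact piecewise closed form
phantom_radial_inverse <- function(spec, rho, A) {
  pc <- phantom_peak_coefs(spec)
  ri <- spec$r_endo; ro <- spec$r_epi
  rmax <- spec$size / 2
  A <- rep_len(A, length(rho))
  at <- A * pc$a; bt <- 1 + A * (pc$b - 1)
  rho_i <- sqrt(bt * ri^2 - at)
  rho_o <- sqrt(bt * ro^2 - at)
  out <- rho
  core <- rho <= rho_i
  out[core] <- rho[core] * (ri / rho_i[core])
  ann <- rho > rho_i & rho <= rho_o
  out[ann] <- sqrt((rho[ann]^2 + at[ann]) / bt[ann])
  ext <- rho > rho_o & rho < rmax
  if (any(ext)) {
    cc <- (rho_o[ext] - ro) / (rmax - ro)^2
    disc <- pmax(1 - 4 * cc * (rmax - rho[ext]), 0)
    s <- ifelse(abs(cc) < 1e-12, rmax - rho[ext],
                (1 - sqrt(disc)) / (2 * cc))
    out[ext] <- rmax - s
  }
  out
}

phantom_twist_at <- function(spec, r) {
  (spec$rotation_deg + spec$twist_deg * pmin(r / spec$r_epi, 1)) * pi / 180
}

#' Forward displacement of the phantom deformation
#'
#' Displacement (pixels) mapping reference-frame (end-diastolic) points to
#' their position at the given frame: the analytic ground truth the
#' registration is asked to recover.
#'
#' @param spec a [phantom_spec()].
#' @param frame frame index (0-based).
#' @param points n-by-2 matrix of reference (x, y) pixel coordinates.
#' @return n-by-2 matrix of displacements.
#' @export
phantom_displacement <- function(spec, frame, points) {
  p <- as_points(points)
  cen <- phantom_center(spec)
  dx <- p[, 1] - cen[1]; dy <- p[, 2] - cen[2]
  r <- sqrt(dx^2 + dy^2)
  beta <- atan2(dy, dx)
  act <- phantom_activation(spec, frame)
  A <- act * phantom_motion_scale(spec, beta)
  rho <- phantom_radial_map(spec, r, A)
  gam <- beta + act * phantom_twist_at(spec, r)
  cbind(rho * cos(gam) - dx, rho * sin(gam) - dy)
}

#' Dense ground-truth displacement field of a phantom frame
#'
#' @param spec a [phantom_spec()].
#' @param frame frame index (0-based).
#' @return A [displacement_field()] on the reference grid.
#' @export
phantom_field <- function(spec, frame) {
  dims <- c(spec$size, spec$size)
  g <- pixel_grid(dims)
  d <- phantom_displacement(spec, frame,
                            cbind(as.numeric(g$x), as.numeric(g$y)))
  f <- displacement_field(NULL, dims, frame = frame)
  f$u[, , 1] <- matrix(d[, 1], dims[1], dims[2])
  f$u[, , 2] <- matrix(d[, 2], dims[1], dims[2])
  f
}

# analytic reference-frame intensity as a function of material polar coords
phantom_intensity <- function(spec, r, beta) {
  lv <- spec$intensity
  edge <- 0.8
  sm <- function(x) 1 / (1 + exp(-x / edge))
  s1 <- sm(r - spec$r_endo)
  s2 <- sm(r - spec$r_epi)
  bg <- lv[["background"]]
  if (!is.null(spec$weak_edge)) {
    w <- angular_window(beta, spec$weak_edge$center_deg,
                        spec$weak_edge$width_deg)
    bg <- bg + spec$weak_edge$reduction * w * (lv[["myo"]] - lv[["background"]])
  }
  myo <- lv[["myo"]] *
    (1 + spec$texture_amplitude * sin(3 * beta) *
       sin(pi * pmin(pmax((r - spec$r_endo) / (spec$r_epi - spec$r_endo), 0), 1)))
  lv[["cavity"]] * (1 - s1) + myo * s1 * (1 - s2) + bg * s2
}

# material (reference) polar coordinates of target-frame pixels:
# exact inversion of the forward map (fixed point over the twist coupling)
phantom_inverse_polar <- function(spec, frame, x, y) {
  cen <- phantom_center(spec)
  qx <- x - cen[1]; qy <- y - cen[2]
  rho <- sqrt(qx^2 + qy^2)
  gam <- atan2(qy, qx)
  act <- phantom_activation(spec, frame)
  r <- rho
  beta <- gam
  for (it in 1:60) {
    beta_new <- gam - act * phantom_twist_at(spec, r)
    A <- act * phantom_motion_scale(spec, beta_new)
    r_new <- phantom_radial_inverse(spec, rho, A)
    if (max(abs(r_new - r), abs(beta_new - beta)) < 1e-12) {
      r <- r_new; beta <- beta_new; break
    }
    r <- r_new; beta <- beta_new
  }
  list(r = r, beta = beta)
}

#' Generate a phantom cine sequence with ground truth
#'
#' Frames are rendered by evaluating the analytic reference intensity at
#' the exactly inverted deformation, so the intensity motion equals the
#' stated displacement field by construction; Gaussian noise is added last
#' under the spec's seed. Contours and landmarks are advected exactly.
#'
#' @param spec a [phantom_spec()].
#' @param n_contour_points points per ground-truth contour.
#' @return A list with `cine` (a [cine_sequence()]) and `truth`: per-frame
#'   `fields` (list of [displacement_field()]), `contours` (nested list
#'   `[[frame_id]][[label]]` of [contour_point_set()]s), `landmarks`
#'   (list `A`, `B` of frames-by-2 trajectories: A mid-endocardial in the
#'   high-deformation region, B on the weak/low-contrast epicardial edge),
#'   `centroid`, and `mask` (reference myocardium).
#' @export
phantom_generate <- function(spec, n_contour_points = 64L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- c(spec$size, spec$size)
  g <- pixel_grid(dims)
  xs <- as.numeric(g$x); ys <- as.numeric(g$y)
  set.seed(spec$seed)
  frames <- vector("list", spec$frames)
  fields <- vector("list", spec$frames)
  contours <- list()
  cen <- phantom_center(spec)
  ang <- seq(0, 2 * pi, length.out = n_contour_points + 1L)[seq_len(n_contour_points)]
  base_endo <- cbind(cen[1] + spec$r_endo * cos(ang),
                     cen[2] + spec$r_endo * sin(ang))
  base_epi <- cbind(cen[1] + spec$r_epi * cos(ang),
                    cen[2] + spec$r_epi * sin(ang))
  # landmark A: mid-endocardium in the fully contracting region;
  # landmark B: on the epicardial edge, centered on the weak arc if present
  beta_a <- pi / 4
  beta_b <- if (!is.null(spec$weak_edge)) spec$weak_edge$center_deg * pi / 180
            else -pi / 2
  lm_ref <- rbind(A = cen + (spec$r_endo + 1.5) * c(cos(beta_a), sin(beta_a)),
                  B = cen + spec$r_epi * c(cos(beta_b), sin(beta_b)))
  lmA <- matrix(NA_real_, spec$frames, 2)
  lmB <- matrix(NA_real_, spec$frames, 2)
  for (t in seq_len(spec$frames) - 1L) {
    inv <- phantom_inverse_polar(spec, t, xs, ys)
    img <- matrix(phantom_intensity(spec, inv$r, inv$beta), dims[1], dims[2])
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          dims[1], dims[2])
    frames[[t + 1L]] <- img
    fields[[t + 1L]] <- phantom_field(spec, t)
    de <- phantom_displacement(spec, t, base_endo)
    dp <- phantom_displacement(spec, t, base_epi)
    contours[[as.character(t)]] <- list(
      endo = contour_point_set(base_endo + de, label = "endo"),
      epi = contour_point_set(base_epi + dp, label = "epi"))
    lmA[t + 1L, ] <- lm_ref["A", ] +
      phantom_displacement(spec, t, lm_ref["A", , drop = FALSE])
    lmB[t + 1L, ] <- lm_ref["B", ] +
      phantom_displacement(spec, t, lm_ref["B", , drop = FALSE])
  }
  cine <- cine_sequence(frames, pixel_spacing = rep(spec$pixel_spacing, 2L),
                        frame_interval = spec$frame_interval)
  mask <- myocardium_mask(contours[["0"]]$endo, contours[["0"]]$epi, dims)
  list(cine = cine,
       truth = list(fields = fields, contours = contours,
                    landmarks = list(A = lmA, B = lmB, reference = lm_ref),
                    centroid = cen, mask = mask, spec = spec))
}

#' Analytic Green radial strain of the phantom deformation
#'
#' Closed-form strain of the programmed deformation: the squared stretch of
#' a material radial fiber is \eqn{(\partial\rho/\partial r)^2 +
#' (\rho\,\partial\psi/\partial r)^2} (radial thinning/thickening plus the
#' shear contributed by a radius-dependent twist), and the Green radial
#' strain is half its excess over 1. Evaluated on the myocardial annulus.
#'
#' @param spec a [phantom_spec()].
#' @param frame frame index (0-based).
#' @param points n-by-2 reference coordinates (default: all pixels).
#' @return Radial strain (fraction, not percent) at the points; `NA`
#'   outside the annulus.
#' @export
analytic_radial_strain <- function(spec, frame, points = NULL) {
  if (is.null(points)) {
    g <- pixel_grid(c(spec$size, spec$size))
    points <- cbind(as.numeric(g$x), as.numeric(g$y))
  }
  p <- as_points(points)
  cen <- phantom_center(spec)
  dx <- p[, 1] - cen[1]; dy <- p[, 2] - cen[2]
  r <- sqrt(dx^2 + dy^2)
  beta <- atan2(dy, dx)
  act <- phantom_activation(spec, frame)
  A <- act * phantom_motion_scale(spec, beta)
  pc <- phantom_peak_coefs(spec)
  e <- rep(NA_real_, length(r))
  ann <- r >= spec$r_endo & r <= spec$r_epi
  if (any(ann)) {
    at <- A[ann] * pc$a; bt <- 1 + A[ann] * (pc$b - 1)
    rho <- sqrt(bt * r[ann]^2 - at)
    drho <- bt * r[ann] / rho
    # twist derivative (linear profile below r_epi)
    dpsi <- act * ifelse(r[ann] < spec$r_epi,
                         spec$twist_deg * pi / 180 / spec$r_epi, 0)
    e[ann] <- 0.5 * (drho^2 + (rho * dpsi)^2 - 1)
  }
  e
}

#' Render the phantom reference deformed by a known affine
#'
#' Produces the frame seen when the reference anatomy is moved by the given
#' global transform (the image is the analytic reference intensity sampled
#' at the exact affine inverse, so there is no interpolation error), with
#' fresh noise. Used to validate the global registration stage against a
#' known ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param affine an [affine_params()] mapping reference to target
#'   coordinates.
#' @param noise_sd noise level (defaults to the spec's).
#' @param seed noise seed (defaults to the spec's seed + 1).
#' @return An image matrix.
#' @export
phantom_affine_frame <- function(spec, affine, noise_sd = spec$noise_sd,
                                 seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(affine, "affine_params"))
  g <- pixel_grid(c(spec$size, spec$size))
  qx <- as.numeric(g$x) - affine$dx
  qy <- as.numeric(g$y) - affine$dy
  ct <- cos(affine$theta); st <- sin(affine$theta)
  # inverse of k R(theta) p + d:  p = R(-theta) (q - d) / k
  px <- (ct * qx - st * qy) / affine$k
  py <- (st * qx + ct * qy) / affine$k
  cen <- phantom_center(spec)
  r <- sqrt((px - cen[1])^2 + (py - cen[2])^2)
  beta <- atan2(py - cen[2], px - cen[1])
  img <- matrix(phantom_intensity(spec, r, beta), spec$size, spec$size)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        spec$size, spec$size)
  }
  img
}

#' Derive a weak-edge variant of a phantom spec
#'
#' Lowers the myocardium/background contrast along an arc of the
#' epicardium, reproducing the weak-edge failure mode that motivates the
#' contour-correspondence penalty. `reduction = 0` leaves the spec
#' unchanged; `reduction = 1` makes the epicardial step vanish within the
#' arc (undetectable by an intensity gradient under noise).
#'
#' @param spec a [phantom_spec()].
#' @param center_deg arc center angle (degrees).
#' @param width_deg arc width (degrees).
#' @param reduction contrast reduction in [0, 1].
#' @return A modified [phantom_spec()].
#' @export
weak_edge_variant <- function(spec, center_deg = -90, width_deg = 70,
                              reduction = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (reduction < 0 || reduction > 1) stop("'reduction' must be in [0, 1]")
  spec$weak_edge <- list(center_deg = center_deg, width_deg = width_deg,
                         reduction = reduction)
  spec
}
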