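#' Deformation gradient tensor from a displacement field
#'
#' \eqn{F = I + \nabla u} computed in physical units (mm) by central finite
#' differences, one-sided at image borders. If the field contains
#' non-finite values (masked-out pixels), pixels whose difference stencil
#' touches them are dropped (set to `NA`) with a warning.
#'
#' @param field a [displacement_field()] or a `nrow x ncol x 2` array of
#'   pixel displacements (x then y component).
#' @param spacing pixel spacing in mm, length 1 or 2 `(x, y)`.
#' @return A `nrow x ncol x 2 x 2` array; `[ , , i, j]` is
#'   \eqn{\partial x'_i / \partial x_j} with axis 1 = x, axis 2 = y.
#' @export
deformation_gradient <- function(field, spacing = c(1, 1)) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  stopifnot(is.array(u), length(dim(u)) == 3L, dim(u)[3] == 2L)
  spacing <- rep_len(as.numeric(spacing), 2L)
  nr <- dim(u)[1]; nc <- dim(u)[2]
  ddx <- function(m) { # d/dx (along columns), central, one-sided at edges
    out <- (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / 2
    out[, 1] <- m[, 2] - m[, 1]
    out[, nc] <- m[, nc] - m[, nc - 1]
    out
  }
  ddy <- function(m) {
    out <- (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / 2
    out[1, ] <- m[2, ] - m[1, ]
    out[nr, ] <- m[nr, ] - m[nr - 1, ]
    out
  }
  ux <- u[, , 1]; uy <- u[, , 2]
  f <- array(0, dim = c(nr, nc, 2L, 2L))
  # physical-units chain rule: d(u_i s_i)/d(x_j s_j) = (s_i/s_j) du_i/dx_j
  f[, , 1, 1] <- 1 + ddx(ux)
  f[, , 1, 2] <- (spacing[1] / spacing[2]) * ddy(ux)
  f[, , 2, 1] <- (spacing[2] / spacing[1]) * ddx(uy)
  f[, , 2, 2] <- 1 + ddy(uy)
  if (anyNA(f) || any(!is.finite(f))) {
    warning("non-finite displacements: affected pixels dropped from the tensor")
    f[!is.finite(f)] <- NA_real_
  }
  f
}

#' Green-Lagrange strain tensor
#'
#' \eqn{E = (F^T F - I)/2}, computed per pixel. Finite-deformation correct
#' and exactly zero under rigid rotation.
#'
#' @param f deformation gradient array from [deformation_gradient()].
#' @return List of matrices `E_xx`, `E_xy`, `E_yy` (the symmetric tensor,
#'   off-diagonal stored once).
#' @export
strain_tensor <- function(f) {
  stopifnot(length(dim(f)) == 4L)
  f11 <- f[, , 1, 1]; f12 <- f[, , 1, 2]
  f21 <- f[, , 2, 1]; f22 <- f[, , 2, 2]
  list(E_xx = (f11^2 + f21^2 - 1) / 2,
       E_xy = (f11 * f12 + f21 * f22) / 2,
       E_yy = (f12^2 + f22^2 - 1) / 2)
}

radial_directions <- function(dim, centroid, spacing = c(1, 1)) {
  g <- pixel_grid(dim)
  spacing <- rep_len(as.numeric(spacing), 2L)
  rx <- (g$x - centroid[1]) * spacing[1]
  ry <- (g$y - centroid[2]) * spacing[2]
  nrm <- sqrt(rx^2 + ry^2)
  list(rx = rx / nrm, ry = ry / nrm, r = nrm)
}

#' Radial and circumferential strain projections
#'
#' Projects the strain tensor on the unit radial direction from the LV
#' centroid, \eqn{e_r = \hat r^T E \hat r} (and the tangential analogue),
#' reported in percent. Positive radial strain is wall thickening
#' (tension), negative is compression. The engineering-strain reading of
#' "percent thickness variation", \eqn{\sqrt{\hat r^T F^T F \hat r} - 1},
#' is emitted alongside; the Green value is the default used elsewhere.
#'
#' @param E strain tensor list from [strain_tensor()].
#' @param centroid LV centroid (x, y) in pixel coordinates.
#' @param spacing pixel spacing in mm (for the radial direction geometry).
#' @return List of matrices `radial_pct`, `circ_pct`, `radial_eng_pct`
#'   (all percent; the centroid pixel is `NA`).
#' @export
radial_strain <- function(E, centroid, spacing = c(1, 1)) {
  dims <- dim(E$E_xx)
  d <- radial_directions(dims, centroid, spacing)
  er <- d$rx^2 * E$E_xx + 2 * d$rx * d$ry * E$E_xy + d$ry^2 * E$E_yy
  # tangent = radial rotated 90 degrees
  ec <- d$ry^2 * E$E_xx - 2 * d$rx * d$ry * E$E_xy + d$rx^2 * E$E_yy
  # engineering radial stretch from C = 2E + I
  stretch2 <- 2 * er + 1
  eng <- sqrt(pmax(stretch2, 0)) - 1
  at_c <- d$r == 0
  er[at_c] <- NA; ec[at_c] <- NA; eng[at_c] <- NA
  list(radial_pct = 100 * er, circ_pct = 100 * ec,
       radial_eng_pct = 100 * eng)
}

#' Per-pixel strain field of one frame
#'
#' Convenience wrapper chaining [deformation_gradient()],
#' [strain_tensor()] and [radial_strain()] over a myocardium mask.
#'
#' @param field a [displacement_field()] or displacement array.
#' @param centroid LV centroid (x, y) in pixels (fixed at the reference
#'   frame across the cycle).
#' @param spacing pixel spacing in mm.
#' @param mask logical myocardium mask (reference frame); `NULL` keeps the
#'   full image.
#' @return An object of class `strain_field` with matrices `radial_pct`,
#'   `circ_pct`, `radial_eng_pct`, `E_xx`, `E_xy`, `E_yy`, plus `frame`,
#'   `mask`, `centroid`.
#' @export
strain_field <- function(field, centroid, spacing = c(1, 1), mask = NULL) {
  f <- deformation_gradient(field, spacing)
  E <- strain_tensor(f)
  pr <- radial_strain(E, centroid, spacing)
  frame <- if (inherits(field, "displacement_field")) field$frame else NA_integer_
  if (is.null(mask)) mask <- matrix(TRUE, dim(E$E_xx)[1], dim(E$E_xx)[2])
  structure(c(pr, E, list(frame = frame, mask = mask, centroid = centroid)),
            class = "strain_field")
}

#' Strain rate by temporal finite differences
#'
#' Central differences of a strain time series over uniformly sampled cine
#' frames, one-sided at the sequence ends; units 1/s when the input strain
#' is dimensionless (fractional).
#'
#' @param series numeric vector (one value per frame) or frames-by-series
#'   matrix of strain values.
#' @param frame_interval scalar frame interval in ms; a vector of per-frame
#'   intervals is rejected unless constant (cine sampling is uniform).
#' @return Derivative with the same shape as `series`.
#' @export
strain_rate <- function(series, frame_interval) {
  if (length(frame_interval) > 1L) {
    if (diff(range(frame_interval)) > 1e-9)
      stop("non-uniform frame interval; cine sampling must be uniform")
    frame_interval <- frame_interval[1]
  }
  m <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  nf <- nrow(m)
  if (nf < 3L) stop("strain rate needs at least 3 frames")
  dt <- frame_interval / 1000
  out <- (rbind(m[-1, , drop = FALSE], m[nf, , drop = FALSE]) -
            rbind(m[1, , drop = FALSE], m[-nf, , drop = FALSE])) /
    (2 * dt)
  out[1, ] <- (m[2, ] - m[1, ]) / dt
  out[nf, ] <- (m[nf, ] - m[nf - 1, ]) / dt
  if (is.matrix(series)) out else drop(out)
}

#' AHA segment model for a short-axis slice
#'
#' Partitions the myocardium mask into the AHA 17-segment model sectors for
#' one short-axis level: 6 sectors of 60 degrees for basal (labels 1-6) and
#' mid (7-12), 4 sectors of 90 degrees for apical (13-16). Segment 17 (the
#' apex cap) has no short-axis representation. Sectors run counterclockwise
#' (with the y axis pointing up) from the anterior RV insertion angle.
#'
#' @param mask logical myocardium mask (annular).
#' @param centroid LV centroid (x, y) in pixels.
#' @param rv_insertion_angle anterior RV insertion angle in radians
#'   (measured counterclockwise from the +x axis, y up).
#' @param level `"basal"`, `"mid"` or `"apical"`.
#' @return An object of class `segment_model`: `labels` (integer matrix, 0
#'   outside the mask), `centroid`, `rv_insertion_angle`, `level`,
#'   `segment_ids`.
#' @export
aha_segments <- function(mask, centroid, rv_insertion_angle = 0,
                         level = c("basal", "mid", "apical")) {
  level <- match.arg(level)
  stopifnot(is.matrix(mask), is.logical(mask))
  nsec <- if (level == "apical") 4L else 6L
  base <- switch(level, basal = 0L, mid = 6L, apical = 12L)
  g <- pixel_grid(dim(mask))
  # y-up angle so "counterclockwise" matches the displayed anatomy
  ang <- atan2(-(g$y - centroid[2]), g$x - centroid[1])
  off <- (ang - rv_insertion_angle) %% (2 * pi)
  sec <- pmin(floor(off / (2 * pi / nsec)), nsec - 1)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[mask] <- base + 1L + as.integer(sec[mask])
  ids <- base + seq_len(nsec)
  present <- ids %in% unique(labels[mask])
  if (!all(present))
    stop("empty AHA segment(s): ", paste(ids[!present], collapse = ", "))
  structure(list(labels = labels, centroid = centroid,
                 rv_insertion_angle = rv_insertion_angle, level = level,
                 segment_ids = ids),
            class = "segment_model")
}

#' Segmental strain and strain-rate time curves
#'
#' Averages the radial (and circumferential) strain over each AHA segment
#' for every frame, adds the global mean (area-weighted over the mask,
#' reported as `segment_id = 0`), and appends strain-rate curves from
#' [strain_rate()]. A segment emptied by mask erosion at some frame yields
#' `NA` for that frame (a recorded gap, never interpolated).
#'
#' @param seq_or_fields a `displacement_sequence` from
#'   [extract_displacement_sequence()], or a list of
#'   [displacement_field()]s.
#' @param model a [segment_model()].
#' @param spacing pixel spacing in mm (taken from the sequence if present).
#' @param frame_interval frame interval in ms (likewise).
#' @return A tibble with columns `frame`, `time_ms`, `level`, `segment_id`,
#'   `radial_strain_pct`, `circ_strain_pct`, `radial_strain_rate_per_s`.
#' @export
segment_curves <- function(seq_or_fields, model, spacing = NULL,
                           frame_interval = NULL) {
  stopifnot(inherits(model, "segment_model"))
  fields <- if (inherits(seq_or_fields, "displacement_sequence")) {
    if (is.null(spacing)) spacing <- seq_or_fields$pixel_spacing
    if (is.null(frame_interval))
      frame_interval <- seq_or_fields$frame_interval
    seq_or_fields$fields
  } else seq_or_fields
  if (is.null(spacing)) spacing <- c(1, 1)
  if (is.null(frame_interval)) frame_interval <- 50
  mask <- model$labels > 0L
  nf <- length(fields)
  ids <- model$segment_ids
  seg_rad <- matrix(NA_real_, nf, length(ids))
  seg_circ <- matrix(NA_real_, nf, length(ids))
  glob_rad <- numeric(nf); glob_circ <- numeric(nf)
  for (t in seq_len(nf)) {
    sf <- strain_field(fields[[t]], model$centroid, spacing, mask)
    for (j in seq_along(ids)) {
      sel <- model$labels == ids[j]
      vr <- sf$radial_pct[sel]; vc <- sf$circ_pct[sel]
      seg_rad[t, j] <- if (all(is.na(vr))) NA_real_ else mean(vr, na.rm = TRUE)
      seg_circ[t, j] <- if (all(is.na(vc))) NA_real_ else mean(vc, na.rm = TRUE)
    }
    glob_rad[t] <- mean(sf$radial_pct[mask], na.rm = TRUE)
    glob_circ[t] <- mean(sf$circ_pct[mask], na.rm = TRUE)
  }
  rad_all <- cbind(glob_rad, seg_rad)
  circ_all <- cbind(glob_circ, seg_circ)
  rate <- strain_rate(rad_all / 100, frame_interval)
  all_ids <- c(0L, ids)
  tibble::tibble(
    frame = rep(seq_len(nf) - 1L, times = length(all_ids)),
    time_ms = rep((seq_len(nf) - 1L) * frame_interval, times = length(all_ids)),
    level = model$level,
    segment_id = rep(all_ids, each = nf),
    radial_strain_pct = as.numeric(rad_all),
    circ_strain_pct = as.numeric(circ_all),
    radial_strain_rate_per_s = as.numeric(rate))
}

point_in_polygon <- function(px, py, poly) {
  # even-odd crossing number, vectorized over query points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Myocardium mask between endo- and epicardial contours
#'
#' Pixels inside the epicardial polygon and outside the endocardial one.
#'
#' @param endo,epi [contour_point_set()]s or n-by-2 point matrices.
#' @param dim image dimension `c(nrow, ncol)`.
#' @return Logical matrix.
#' @export
myocardium_mask <- function(endo, epi, dim) {
  pe <- if (inherits(endo, "contour_point_set")) endo$points else as_points(endo)
  pp <- if (inherits(epi, "contour_point_set")) epi$points else as_points(epi)
  g <- pixel_grid(dim)
  px <- as.numeric(g$x); py <- as.numeric(g$y)
  m <- point_in_polygon(px, py, pp) & !point_in_polygon(px, py, pe)
  matrix(m, dim[1], dim[2])
}

#' Centroid of a contour
#'
#' Mean of the contour points; with uniform arc-length resampling this is
#' the standard reference-frame LV centroid.
#'
#' @param contour a [contour_point_set()] or n-by-2 matrix.
#' @return Length-2 numeric (x, y) in pixels.
#' @export
contour_centroid <- function(contour) {
  p <- if (inherits(contour, "contour_point_set")) contour$points
       else as_points(contour)
  colMeans(p)
}
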