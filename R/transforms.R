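#' Global affine transform parameters
#'
#' Scaled rotation plus translation describing the global component of left
#' ventricular motion between the end-diastolic reference frame and a target
#' frame. The rotation matrix convention is
#' \eqn{R(\theta) = [[\cos\theta, \sin\theta], [-\sin\theta, \cos\theta]]},
#' which in a y-down image coordinate system rotates clockwise for positive
#' \eqn{\theta}; this is kept as-is and documented rather than "corrected".
#'
#' @param k scale factor, must be positive (1 = no scaling).
#' @param theta rotation angle in radians, in (-pi, pi].
#' @param dx,dy translation in pixels.
#' @return An object of class `affine_params`.
#' @examples
#' p <- affine_params(k = 1.05, theta = 0.1, dx = 3, dy = -2)
#' affine_apply(p, c(10, 10))
#' @export
affine_params <- function(k = 1, theta = 0, dx = 0, dy = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("scale factor 'k' must be positive")
  if (!is.finite(theta) || theta <= -pi || theta > pi)
    stop("'theta' must lie in (-pi, pi]")
  structure(list(k = as.numeric(k), theta = as.numeric(theta),
                 dx = as.numeric(dx), dy = as.numeric(dy)),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("affine: k = %.6g, theta = %.6g rad, translation = (%.6g, %.6g) px\n",
              x$k, x$theta, x$dx, x$dy))
  invisible(x)
}

as_points <- function(point) {
  if (is.null(dim(point))) {
    stopifnot(length(point) == 2L)
    point <- matrix(point, nrow = 1L)
  }
  stopifnot(ncol(point) == 2L)
  storage.mode(point) <- "double"
  point
}

#' Apply the global affine transform
#'
#' Maps points as \eqn{k R(\theta) (x, y)^T + (\Delta x, \Delta y)^T}.
#'
#' @param params an [affine_params()] object.
#' @param point a length-2 vector or an n-by-2 matrix of (x, y) pixel
#'   coordinates.
#' @return Transformed coordinates, same shape as `point`.
#' @export
affine_apply <- function(params, point) {
  stopifnot(inherits(params, "affine_params"))
  p <- as_points(point)
  if (!all(is.finite(p))) stop("coordinates must be finite")
  ct <- cos(params$theta); st <- sin(params$theta)
  out <- cbind(params$k * (ct * p[, 1] + st * p[, 2]) + params$dx,
               params$k * (-st * p[, 1] + ct * p[, 2]) + params$dy)
  if (is.null(dim(point))) drop(out) else out
}

#' Global displacement of a point
#'
#' The displacement form of the affine model: `affine_apply(point) - point`.
#'
#' @inheritParams affine_apply
#' @return Displacement vector(s) in pixels, same shape as `point`.
#' @export
global_displacement <- function(params, point) {
  p <- as_points(point)
  out <- affine_apply(params, p) - p
  if (is.null(dim(point))) drop(out) else out
}

#' Cubic B-spline basis function
#'
#' The four cubic uniform B-spline basis polynomials on the local fraction
#' `u` of a knot interval:
#' \deqn{B_0 = (1-u)^3/6,\; B_1 = (3u^3-6u^2+4)/6,\;
#'       B_2 = (-3u^3+3u^2+3u+1)/6,\; B_3 = u^3/6.}
#'
#' @param m basis index, one of 0, 1, 2, 3.
#' @param u local fraction, in `[0, 1)`. Vectorized over `u`.
#' @return Basis weight(s).
#' @export
bspline_basis <- function(m, u) {
  if (!(length(m) == 1L && m %in% 0:3)) stop("'m' must be one of 0, 1, 2, 3")
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)")
  switch(as.character(m),
         "0" = (1 - u)^3 / 6,
         "1" = (3 * u^3 - 6 * u^2 + 4) / 6,
         "2" = (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
         "3" = u^3 / 6)
}

#' Free-form deformation control lattice
#'
#' A quadrilateral mesh of `nx` by `ny` control points with spacing `delta`
#' (pixels per knot interval) anchored at `origin` in image coordinates.
#' Each control point carries a 2-vector displacement; the dense deformation
#' is the tensor-product cubic B-spline interpolation of the lattice.
#' A point at image coordinate x uses control columns
#' `floor((x-origin)/delta) - 1 .. + 2` (0-based), so a full 4x4 support
#' neighbourhood is required — hence `nx, ny >= 4`.
#'
#' @param phi numeric array `nx x ny x 2` of control displacements in pixels
#'   (`[ , , 1]` = x component, `[ , , 2]` = y), or `NULL` for an all-zero
#'   lattice of shape `nx x ny`.
#' @param delta spacing per axis in pixels (length 1 or 2, positive).
#' @param origin lattice anchor (x, y) in image coordinates.
#' @param nx,ny lattice size when `phi` is `NULL`.
#' @return An object of class `ffd_grid`.
#' @seealso [default_ffd_grid()] to build a lattice covering an image.
#' @export
ffd_grid <- function(phi = NULL, delta = 8, origin = c(0, 0),
                     nx = NULL, ny = NULL) {
  delta <- rep_len(as.numeric(delta), 2L)
  if (any(delta <= 0)) stop("'delta' must be positive")
  if (is.null(phi)) {
    stopifnot(!is.null(nx), !is.null(ny))
    phi <- array(0, dim = c(nx, ny, 2L))
  }
  stopifnot(is.array(phi), length(dim(phi)) == 3L, dim(phi)[3] == 2L)
  if (dim(phi)[1] < 4L || dim(phi)[2] < 4L)
    stop("lattice must be at least 4 x 4 control points")
  structure(list(phi = phi, delta = delta,
                 origin = as.numeric(origin)),
            class = "ffd_grid")
}

#' Build an FFD lattice covering an image with full support
#'
#' Pads the lattice by one ring of control points beyond the image so that
#' every in-image pixel has the full 4x4 B-spline support; padding control
#' points are ordinary optimizable parameters.
#'
#' @param dim image dimension `c(nrow, ncol)` (rows = y, cols = x).
#' @param delta control-point spacing in pixels (length 1 or 2).
#' @return An all-zero [ffd_grid()] whose support contains the image.
#' @export
default_ffd_grid <- function(dim, delta = 8) {
  delta <- rep_len(as.numeric(delta), 2L)
  nc <- dim[2]; nr <- dim[1]
  # origin = -delta puts pixel x = 0 at lattice coordinate 1
  nx <- floor((nc - 1) / delta[1]) + 4L
  ny <- floor((nr - 1) / delta[2]) + 4L
  ffd_grid(delta = delta, origin = -delta, nx = nx, ny = ny)
}

#' Evaluate the FFD displacement
#'
#' Tensor-product cubic B-spline interpolation of the control lattice:
#' \deqn{T_{local}(x,y) = \sum_{n=0}^{3}\sum_{m=0}^{3}
#'   B_m(u) B_n(v)\, \phi_{i+m, j+n}}
#' with `i = floor(sx) - 1`, `u = sx - floor(sx)`, `sx = (x - origin)/delta`
#' (and likewise j, v). Points whose 4x4 support falls outside the lattice
#' raise an error; there is no silent clamping.
#'
#' @param grid an [ffd_grid()].
#' @param point a length-2 vector or n-by-2 matrix of (x, y) coordinates.
#' @return Displacement in pixels, same shape as `point`.
#' @export
ffd_displacement <- function(grid, point) {
  stopifnot(inherits(grid, "ffd_grid"))
  p <- as_points(point)
  out <- .cpp_ffd_disp(grid$phi[, , 1], grid$phi[, , 2],
                       grid$delta, grid$origin, p[, 1], p[, 2])
  if (anyNA(out))
    stop("point outside the FFD lattice support (4x4 neighbourhood incomplete)")
  if (is.null(dim(point))) drop(out) else out
}

#' Hierarchical (affine + FFD) transform
#'
#' The combined transformation adds the global and local models as
#' displacement fields: `T(p) = p + T_global(p) + T_local(p)`. Note this is
#' additive in displacements, not a functional composition of the two maps;
#' the two differ for large affines.
#'
#' @param affine an [affine_params()].
#' @param grid an [ffd_grid()].
#' @return An object of class `hierarchical_transform`.
#' @export
hierarchical_transform <- function(affine, grid) {
  stopifnot(inherits(affine, "affine_params"), inherits(grid, "ffd_grid"))
  structure(list(affine = affine, grid = grid),
            class = "hierarchical_transform")
}

#' Apply a hierarchical transform to points
#'
#' @param t a [hierarchical_transform()].
#' @param point a length-2 vector or n-by-2 matrix of (x, y) coordinates.
#' @return Mapped coordinates `point + T_global(point) + T_local(point)`.
#' @export
combined_apply <- function(t, point) {
  stopifnot(inherits(t, "hierarchical_transform"))
  p <- as_points(point)
  out <- p + global_displacement(t$affine, p) + ffd_displacement(t$grid, p)
  if (is.null(dim(point))) drop(out) else out
}

#' Serialize an FFD lattice to JSON
#'
#' Writes lattice shape, spacing, origin and the flattened control
#' displacements so a registration result is a portable text artifact.
#'
#' @param grid an [ffd_grid()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
ffd_grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "ffd_grid"))
  obj <- list(nx = dim(grid$phi)[1], ny = dim(grid$phi)[2],
              delta = grid$delta, origin = grid$origin,
              phi = as.numeric(grid$phi))
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Deserialize an FFD lattice from JSON
#'
#' @param x a file path or a JSON string produced by [ffd_grid_to_json()].
#' @return An [ffd_grid()].
#' @export
ffd_grid_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  phi <- array(obj$phi, dim = c(obj$nx, obj$ny, 2L))
  ffd_grid(phi = phi, delta = obj$delta, origin = obj$origin)
}

#' Serialize a hierarchical transform to JSON
#'
#' @param t a [hierarchical_transform()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "hierarchical_transform"))
  obj <- list(affine = list(k = t$affine$k, theta = t$affine$theta,
                            dx = t$affine$dx, dy = t$affine$dy),
              grid = list(nx = dim(t$grid$phi)[1], ny = dim(t$grid$phi)[2],
                          delta = t$grid$delta, origin = t$grid$origin,
                          phi = as.numeric(t$grid$phi)))
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Deserialize a hierarchical transform from JSON
#'
#' @param x a file path or JSON string produced by [transform_to_json()].
#' @return A [hierarchical_transform()].
#' @export
transform_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  aff <- affine_params(k = obj$affine$k, theta = obj$affine$theta,
                       dx = obj$affine$dx, dy = obj$affine$dy)
  grid <- ffd_grid(phi = array(obj$grid$phi,
                               dim = c(obj$grid$nx, obj$grid$ny, 2L)),
                   delta = obj$grid$delta, origin = obj$grid$origin)
  hierarchical_transform(aff, grid)
}
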