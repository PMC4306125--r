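#' Optimizer configuration for gradient-descent registration
#'
#' The update rule is \eqn{\mu^{k+1} = \mu^k - a\, g(\mu^k)} with a constant
#' gain. When `gain` is `NULL` the gain is set once, from the gradient at the
#' starting point, so that the first step moves each parameter group by
#' `step0` (its natural unit: pixels for translations and control points,
#' radians for the angle), and is then held constant apart from the
#' safeguard: a step that increases the cost (or makes it non-finite) is
#' rejected and the gain halved.
#'
#' @param gain constant gain factor(s), recycled over parameters; `NULL`
#'   for the auto-scaled constant described above.
#' @param step0 desired first-step size per parameter group (used when
#'   `gain` is `NULL`), recycled over parameters.
#' @param max_iterations iteration budget.
#' @param tolerance minimum cost decrease to continue; `NULL` means
#'   `1e-6` times the initial cost.
#' @param gradient_step central finite-difference step per parameter,
#'   recycled.
#' @param seed RNG seed for any stochastic choices (none in the default
#'   pipeline; recorded for reproducibility).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(gain = NULL, step0 = 0.5,
                             max_iterations = 200L, tolerance = NULL,
                             gradient_step = 0.01, seed = 1L) {
  if (!is.null(gain) && any(gain <= 0)) stop("'gain' must be positive")
  if (!is.null(tolerance) && tolerance < 0) stop("'tolerance' must be >= 0")
  structure(list(gain = gain, step0 = step0,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 gradient_step = gradient_step, seed = as.integer(seed)),
            class = "optimizer_config")
}

central_fd_gradient <- function(fn, mu, h) {
  h <- rep_len(h, length(mu))
  g <- numeric(length(mu))
  for (i in seq_along(mu)) {
    up <- mu; up[i] <- up[i] + h[i]
    dn <- mu; dn[i] <- dn[i] - h[i]
    g[i] <- (fn(up) - fn(dn)) / (2 * h[i])
  }
  g
}

#' Constant-gain gradient descent with finite-difference gradients
#'
#' Minimizes `cost_fn` from `mu0` by steepest descent,
#' \eqn{\mu^{k+1} = \mu^k - a\, g(\mu^k)}, with the gradient computed by
#' central finite differences. Steps that raise the cost or make it
#' non-finite are rejected with the gain halved; after an accepted step the
#' gain recovers gradually (factor 1.2, capped at its calibrated value), so
#' one early rejection does not cripple the remaining search. The iteration
#' stops when the cost decrease stays below the tolerance over three
#' consecutive iterations (a single small decrease is a normal zigzag step
#' of an ill-conditioned descent, not convergence), the budget is
#' exhausted, or the gain underflows. The best-seen parameters are
#' returned.
#'
#' @param cost_fn scalar function of a parameter vector, finite at `mu0`.
#' @param mu0 starting parameter vector.
#' @param config an [optimizer_config()].
#' @return A list with `mu` (best-seen parameters), `cost`, `iterations`,
#'   `converged`, and `trajectory` (tibble of iteration and accepted cost).
#' @export
gradient_descent <- function(cost_fn, mu0, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  mu <- as.numeric(mu0)
  cost <- cost_fn(mu)
  if (!is.finite(cost)) stop("cost is not finite at the starting point")
  # default stop: relative to the *current* cost (as in the FFD stage) — a
  # threshold scaled to the large initial misalignment cost is orders of
  # magnitude too loose once the search is near the noise floor
  rel_tol <- is.null(config$tolerance)
  tol <- if (rel_tol) 1e-6 * abs(cost) else config$tolerance
  h <- rep_len(config$gradient_step, length(mu))
  traj_it <- 0L; traj_cost <- cost
  best_mu <- mu; best_cost <- cost
  gain <- config$gain
  gain0 <- NULL
  converged <- FALSE
  stall <- 0L
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    g <- central_fd_gradient(cost_fn, mu, h)
    if (max(abs(g)) == 0) { converged <- TRUE; break }
    if (is.null(gain)) {
      step0 <- rep_len(config$step0, length(mu))
      gain <- step0 / pmax(abs(g), max(abs(g)) * 1e-8)
      gain <- pmin(gain, step0 / (max(abs(g)) * 1e-4))
    } else {
      gain <- rep_len(gain, length(mu))
    }
    if (is.null(gain0)) gain0 <- gain
    repeat {
      prop <- mu - gain * g
      cost_new <- cost_fn(prop)
      if (is.finite(cost_new) && cost_new <= cost) break
      gain <- gain / 2
      if (max(gain * abs(g)) < 1e-12) {
        if (!is.finite(cost_new))
          stop("gain underflow while rejecting non-finite cost steps")
        cost_new <- cost; prop <- mu
        break
      }
    }
    decrease <- cost - cost_new
    mu <- prop; cost <- cost_new
    if (decrease > 0) gain <- pmin(gain * 1.2, gain0)
    traj_it <- c(traj_it, it); traj_cost <- c(traj_cost, cost)
    if (cost < best_cost) { best_cost <- cost; best_mu <- mu }
    if (rel_tol) tol <- 1e-6 * abs(cost)
    stall <- if (decrease < tol) stall + 1L else 0L
    if (stall >= 3L) { converged <- TRUE; break }
  }
  list(mu = best_mu, cost = best_cost, iterations = it, converged = converged,
       trajectory = tibble::tibble(iteration = traj_it, cost = traj_cost))
}

#' Cubic B-spline coefficients of an image
#'
#' Prefilters the image (recursive filter, mirror boundaries) into the
#' interpolating cubic B-spline coefficient array used by [resample()];
#' computing them once per image avoids refiltering inside optimization
#' loops.
#'
#' @param image numeric matrix.
#' @return Coefficient matrix of the same shape, class `spline_coef`.
#' @export
spline_coefficients <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  structure(.cpp_spline_coef(image), class = c("spline_coef", "matrix"))
}

pixel_grid <- function(dim) {
  list(x = matrix(rep(0:(dim[2] - 1L), each = dim[1]), dim[1], dim[2]),
       y = matrix(rep(0:(dim[1] - 1L), times = dim[2]), dim[1], dim[2]))
}

#' Warped sampling coordinates of a transform over an image grid
#'
#' Evaluates the transform at every 0-based pixel coordinate of an image of
#' dimension `dim`, returning the target-frame sampling coordinates used
#' for pull-back resampling.
#'
#' @param transform an [affine_params()] or [hierarchical_transform()].
#' @param dim image dimension `c(nrow, ncol)`.
#' @return A list with coordinate matrices `x`, `y`.
#' @export
warp_coords <- function(transform, dim) {
  g <- pixel_grid(dim)
  pts <- cbind(as.numeric(g$x), as.numeric(g$y))
  mapped <- if (inherits(transform, "affine_params"))
    affine_apply(transform, pts)
  else combined_apply(transform, pts)
  list(x = matrix(mapped[, 1], dim[1], dim[2]),
       y = matrix(mapped[, 2], dim[1], dim[2]))
}

#' Resample an image at arbitrary coordinates by cubic spline interpolation
#'
#' Evaluates the interpolating cubic B-spline model of `image` at the given
#' coordinates. Coordinates outside the image are clamped to the border
#' (so they take the image's border value) and flagged in the `mask`
#' attribute (`TRUE` = originally inside).
#'
#' @param image numeric matrix.
#' @param coords list with matrices (or vectors) `x` and `y` of 0-based
#'   sampling coordinates (x along columns, y along rows).
#' @param coef optional precomputed [spline_coefficients()] of `image`.
#' @return Matrix (or vector) of interpolated intensities with a logical
#'   attribute `mask`.
#' @export
resample <- function(image, coords, coef = NULL) {
  if (is.null(coef)) coef <- spline_coefficients(image)
  x <- coords$x; y <- coords$y
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("sampling coordinates must be finite")
  vals <- .cpp_spline_eval(coef, as.numeric(x), as.numeric(y))
  inside <- as.numeric(x) >= 0 & as.numeric(x) <= ncol(image) - 1 &
    as.numeric(y) >= 0 & as.numeric(y) <= nrow(image) - 1
  if (is.matrix(x)) {
    vals <- matrix(vals, nrow(x), ncol(x))
    inside <- matrix(inside, nrow(x), ncol(x))
  }
  attr(vals, "mask") <- inside
  vals
}

#' Gaussian pre-smoothing for registration
#'
#' Separable Gaussian blur with replicated borders. Registration stages
#' smooth both images slightly before comparing them: interpolating raw
#' sensor noise at fractional offsets lowers its variance and sculpts
#' spurious shallow minima into the SSD landscape; a mild blur makes the
#' noise field smooth so resampling preserves it, besides the usual SNR
#' gain.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; 0 returns the input.
#' @return Smoothed matrix.
#' @export
smooth_image <- function(image, sigma = 1) {
  if (sigma <= 0) return(image)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  conv1 <- function(m) {
    mp <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(image))))
}

#' Global affine registration stage
#'
#' Finds the scale, rotation and translation minimizing the mean SSD of the
#' reference against the affine-resampled target, by constant-gain gradient
#' descent from the identity.
#'
#' @param reference,target image matrices of identical shape.
#' @param config an [optimizer_config()]; the default uses
#'   finite-difference steps of 0.005 for the scale and angle and 0.01 px
#'   for the translations, first-step sizes of 0.002 (scale), 0.002 rad and
#'   0.25 px, and a 500-iteration budget (traversing the shallow coupled
#'   rotation-translation valley of a large motion takes several hundred
#'   constant-gain steps).
#' @param presmooth_sigma Gaussian pre-smoothing applied to both images
#'   before comparison (see [smooth_image()]); 0 disables it.
#' @return An [affine_params()] with the optimization `trajectory`,
#'   `iterations` and `converged` flag attached as attributes.
#' @export
register_global <- function(reference, target, config = NULL,
                            presmooth_sigma = 1) {
  if (!identical(dim(reference), dim(target)))
    stop("reference and target must have identical shapes")
  if (is.null(config))
    config <- optimizer_config(step0 = c(0.002, 0.002, 0.25, 0.25),
                               gradient_step = c(0.005, 0.005, 0.01, 0.01),
                               max_iterations = 500L)
  reference <- smooth_image(reference, presmooth_sigma)
  target <- smooth_image(target, presmooth_sigma)
  coef <- spline_coefficients(target)
  dims <- dim(reference)
  g <- pixel_grid(dims)
  cen <- c((dims[2] - 1) / 2, (dims[1] - 1) / 2)
  px <- as.numeric(g$x) - cen[1]; py <- as.numeric(g$y) - cen[2]
  # optimized about the image center (decouples rotation/scale from
  # translation); converted back to the origin-anchored parameters below
  cost_fn <- function(mu) {
    k <- mu[1]; th <- mu[2]
    if (k <= 0) return(Inf)
    ct <- cos(th); st <- sin(th)
    wx <- k * (ct * px + st * py) + cen[1] + mu[3]
    wy <- k * (-st * px + ct * py) + cen[2] + mu[4]
    w <- resample(target, list(x = wx, y = wy), coef = coef)
    mean((as.numeric(reference) - w)^2)
  }
  fit <- gradient_descent(cost_fn, c(1, 0, 0, 0), config)
  k <- fit$mu[1]; th <- fit$mu[2]
  ct <- cos(th); st <- sin(th)
  out <- affine_params(k = k, theta = th,
                       dx = cen[1] + fit$mu[3] - k * (ct * cen[1] + st * cen[2]),
                       dy = cen[2] + fit$mu[4] - k * (-st * cen[1] + ct * cen[2]))
  attr(out, "trajectory") <- fit$trajectory
  attr(out, "iterations") <- fit$iterations
  attr(out, "converged") <- fit$converged
  out
}

# 4x4 B-spline support weights of the FFD lattice at arbitrary points.
ffd_support_weights <- function(grid, pts) {
  s <- sweep(pts, 2L, grid$origin) %*% diag(1 / grid$delta)
  i0 <- floor(s[, 1]) - 1; j0 <- floor(s[, 2]) - 1
  u <- s[, 1] - floor(s[, 1]); v <- s[, 2] - floor(s[, 2])
  wx <- sapply(0:3, function(m) bspline_basis(m, u))
  wy <- sapply(0:3, function(m) bspline_basis(m, v))
  if (is.null(dim(wx))) { wx <- matrix(wx, 1); wy <- matrix(wy, 1) }
  list(i0 = i0, j0 = j0, wx = wx, wy = wy)
}

# Unit normals of a contour polygon (sign-free: used only as outer
# products), from central-difference tangents over the cyclic neighbours.
contour_normals <- function(points, closed = TRUE) {
  n <- nrow(points)
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  tx <- points[nxt, 1] - points[prv, 1]
  ty <- points[nxt, 2] - points[prv, 2]
  len <- pmax(sqrt(tx^2 + ty^2), 1e-12)
  cbind(ty / len, -tx / len)
}

# Per-control-point 2x2 blocks of the Gauss-Newton Hessian of
# lambda * C_ICP, projected on the contour normals: after re-matching the
# penalty has no tangential stiffness (a slid point re-matches at no
# cost), so only the normal direction is preconditioned. Evaluated at the
# fixed reference contour points, hence constant over the optimization.
icp_phi_hessian <- function(grid, contours_ref, config, alphas) {
  nx <- dim(grid$phi)[1]; ny <- dim(grid$phi)[2]
  H11 <- matrix(0, nx, ny); H12 <- matrix(0, nx, ny); H22 <- matrix(0, nx, ny)
  for (lb in names(contours_ref)) {
    a <- alphas[[lb]]
    if (is.null(a) || a[1] <= 0) next
    pts <- contours_ref[[lb]]$points
    nrm <- contour_normals(pts, contours_ref[[lb]]$closed)
    sup <- ffd_support_weights(grid, pts)
    for (p in seq_len(nrow(pts))) {
      ii <- sup$i0[p] + 1:4; jj <- sup$j0[p] + 1:4
      w2 <- outer(sup$wx[p, ], sup$wy[p, ])^2
      H11[ii, jj] <- H11[ii, jj] + 2 * a[1] * w2 * nrm[p, 1]^2
      H12[ii, jj] <- H12[ii, jj] + 2 * a[1] * w2 * nrm[p, 1] * nrm[p, 2]
      H22[ii, jj] <- H22[ii, jj] + 2 * a[1] * w2 * nrm[p, 2]^2
    }
  }
  list(H11 = config$lambda * H11, H12 = config$lambda * H12,
       H22 = config$lambda * H22)
}

# Analytic gradient (positional part, correspondences and curvatures
# frozen) of lambda * C_ICP with respect to the control displacements.
icp_phi_gradient <- function(grid, transform, contours_ref, contours_target,
                             config, alphas) {
  nx <- dim(grid$phi)[1]; ny <- dim(grid$phi)[2]
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  value <- 0
  for (lb in names(contours_ref)) {
    tgt <- contours_target[[lb]]
    if (is.null(tgt)) next
    moved <- propagate_contour(contours_ref[[lb]], transform,
                               config$refresh_curvature)
    a <- alphas[[lb]]
    m <- icpif_match(tgt, moved, a[1], a[2])
    value <- value + c_icp(m)
    q <- tgt$points[m$match_index, , drop = FALSE]
    resid <- moved$points - q                  # dC/dQ = 2 a1 (Q - q)
    sup <- ffd_support_weights(grid, contours_ref[[lb]]$points)
    for (p in seq_len(nrow(resid))) {
      ii <- sup$i0[p] + 1:4; jj <- sup$j0[p] + 1:4
      w16 <- outer(sup$wx[p, ], sup$wy[p, ])
      gx[ii, jj] <- gx[ii, jj] + 2 * a[1] * resid[p, 1] * w16
      gy[ii, jj] <- gy[ii, jj] + 2 * a[1] * resid[p, 2] * w16
    }
  }
  list(gx = config$lambda * gx, gy = config$lambda * gy, c_icp = value)
}

#' Local B-spline FFD registration stage
#'
#' Optimizes the control-point displacements of the FFD lattice, on top of
#' a fixed global affine, by constant-gain gradient descent on the total
#' cost (mean SSD plus `lambda` times the contour penalty). The SSD
#' gradient is computed by central finite differences per control point,
#' restricted to the point's B-spline support window; the contour-penalty
#' gradient is taken with correspondences (and advected curvatures) frozen
#' within the step, in the usual closest-point majorization fashion.
#'
#' With an active contour term the stage is a two-phase continuation: an
#' intensity-only descent first, then the full cost from that solution, so
#' the correspondence forces act on small residuals instead of depositing
#' their large initial pulls into directions the intensity term cannot
#' observe. The stiff contour-normal directions are preconditioned by the
#' penalty's known curvature, with a per-iteration trust region. The two
#' phases share the configured iteration budget (at most half for the
#' intensity-only phase), so `max_iterations` bounds the total work of the
#' stage whether or not the contour term is active.
#'
#' @param reference,target image matrices of identical shape.
#' @param affine the [affine_params()] from the global stage.
#' @param contours_ref,contours_target optional named lists of
#'   [contour_point_set()] objects (reference and target frame).
#' @param config an [optimizer_config()]; the default allows 500
#'   iterations with a 0.25 px first step and 0.01 px finite-difference
#'   step.
#' @param cost_config a [cost_config()]; `lambda = 0` reproduces the
#'   intensity-only method.
#' @param grid_spacing control-point spacing in pixels (default 8).
#' @param grid optional starting [ffd_grid()] (e.g. a warm start from the
#'   previous frame); default all-zero lattice covering the image.
#' @param presmooth_sigma Gaussian pre-smoothing applied to both images
#'   before comparison (see [smooth_image()]); 0 disables it.
#' @return An [ffd_grid()] with a cost `trajectory` tibble (iteration,
#'   c_sim, c_icp, total), `iterations` and `converged` attached as
#'   attributes; with an active contour term also `warm_iterations`, the
#'   iteration count of the intensity-only continuation stage that
#'   initializes the final descent.
#' @export
register_local <- function(reference, target, affine,
                           contours_ref = NULL, contours_target = NULL,
                           config = NULL, cost_config = lvstrain::cost_config(),
                           grid_spacing = 8, grid = NULL,
                           presmooth_sigma = 1) {
  if (!identical(dim(reference), dim(target)))
    stop("reference and target must have identical shapes")
  if (is.null(config))
    config <- optimizer_config(step0 = 0.25, gradient_step = 0.01,
                               max_iterations = 500L)
  if (is.null(grid)) grid <- default_ffd_grid(dim(reference), grid_spacing)
  # continuation scheme: with the contour term active, first descend the
  # intensity-only cost, then re-descend with the term enabled. The
  # correspondence forces then act on small residuals only; switching the
  # term on at a zero lattice would deposit its large initial pulls into
  # directions the intensity term cannot see (and so never corrects)
  if (cost_config$lambda > 0 && !is.null(contours_ref) &&
      !is.null(contours_target) && length(contours_ref) > 0) {
    # max_iterations bounds the *total* work of the stage: the two phases
    # share it (at most half for the intensity-only phase, the remainder
    # for the full cost), so runs with and without the contour term spend
    # comparable descent effort and stay comparable
    budget <- config$max_iterations
    cfg1 <- config
    cfg1$max_iterations <- as.integer(ceiling(budget / 2))
    cc0 <- cost_config
    cc0$lambda <- 0
    warm <- register_local(reference, target, affine,
                           config = cfg1, cost_config = cc0,
                           grid_spacing = grid_spacing, grid = grid,
                           presmooth_sigma = presmooth_sigma)
    warm_iter <- attr(warm, "iterations")
    warm_gain <- attr(warm, "gain")
    attributes(warm)[c("trajectory", "iterations", "converged",
                       "final_cost", "gain")] <- NULL
    grid <- warm
    cfg2 <- config
    cfg2$max_iterations <- max(1L, as.integer(budget - warm_iter))
    # keep the gain calibrated on the initial large-gradient state: if it
    # were re-estimated from the near-converged gradient it would come out
    # orders of magnitude too large and the second phase would chase noise
    if (is.null(cfg2$gain)) cfg2$gain <- warm_gain
    out <- register_local_stage(reference, target, affine,
                                contours_ref, contours_target,
                                cfg2, cost_config, grid, presmooth_sigma)
    attr(out, "warm_iterations") <- warm_iter
    return(out)
  }
  register_local_stage(reference, target, affine,
                       contours_ref, contours_target,
                       config, cost_config, grid, presmooth_sigma)
}

# single descent pass of the FFD stage (see register_local)
register_local_stage <- function(reference, target, affine,
                                 contours_ref, contours_target,
                                 config, cost_config, grid,
                                 presmooth_sigma) {
  reference <- smooth_image(reference, presmooth_sigma)
  target <- smooth_image(target, presmooth_sigma)
  coef <- spline_coefficients(target)
  dims <- dim(reference)
  base <- warp_coords(affine, dims)
  use_contours <- cost_config$lambda > 0 && !is.null(contours_ref) &&
    !is.null(contours_target) && length(contours_ref) > 0
  alphas <- NULL
  if (use_contours) {
    alphas <- lapply(names(contours_ref), function(lb) {
      a1 <- cost_config$alpha1; a2 <- cost_config$alpha2
      if (is.null(a1) || is.null(a2)) {
        a <- suppressWarnings(
          compute_alpha_weights(contours_target[[lb]], contours_ref[[lb]]))
        c(if (is.null(a1)) a[1] else a1, if (is.null(a2)) a[2] else a2)
      } else c(a1, a2)
    })
    names(alphas) <- names(contours_ref)
  }
  pg <- pixel_grid(dims)
  pgx <- as.numeric(pg$x); pgy <- as.numeric(pg$y)
  eval_cost <- function(phi) {
    g2 <- grid; g2$phi <- phi
    tr <- hierarchical_transform(affine, g2)
    disp <- .cpp_ffd_disp(phi[, , 1], phi[, , 2], grid$delta, grid$origin,
                          pgx, pgy)
    wx <- as.numeric(base$x) + disp[, 1]
    wy <- as.numeric(base$y) + disp[, 2]
    w <- resample(target, list(x = wx, y = wy), coef = coef)
    csim <- mean((as.numeric(reference) - w)^2)
    cicp <- 0
    if (use_contours) {
      if (cost_config$recompute_alpha_each_iteration) {
        cp <- contour_penalty(tr, contours_ref, contours_target,
                              cost_config, alphas)
        cicp <- cp$value
      } else {
        cicp <- icp_phi_gradient(g2, tr, contours_ref, contours_target,
                                 cost_config, alphas)$c_icp
      }
    }
    c(total = csim + cost_config$lambda * cicp, c_sim = csim, c_icp = cicp)
  }
  phi <- grid$phi
  cur <- eval_cost(phi)
  # default stop: relative change of the *current* cost, so an initially
  # large (later collapsing) penalty term does not inflate the threshold
  rel_tol <- is.null(config$tolerance)
  tol <- if (rel_tol) 1e-6 * abs(cur["total"]) else config$tolerance
  best_phi <- phi; best <- cur
  traj <- list(c(0, cur["c_sim"], cur["c_icp"], cur["total"]))
  gain <- config$gain
  h <- config$gradient_step[1]
  # the contour penalty is a quadratic whose curvature along the contour
  # normals can exceed the SSD curvature by orders of magnitude;
  # preconditioning each control point by (1/gain)I + H (H the
  # normal-projected penalty Hessian block) keeps those stiff directions
  # Newton-sized while leaving every intensity-driven direction at the
  # plain constant-gain step, so one shared step factor serves both terms
  Hicp <- if (use_contours) {
    icp_phi_hessian(grid, contours_ref, cost_config, alphas)
  } else NULL
  q <- 1
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    gsim <- .cpp_ffd_ssd_grad(reference, coef, base$x, base$y,
                              phi[, , 1], phi[, , 2],
                              grid$delta, grid$origin, h)
    garr <- array(gsim, dim = dim(phi))
    if (is.null(gain)) {
      gmax_sim <- max(abs(garr))
      gain <- if (gmax_sim > 0) config$step0[1] / gmax_sim else 1
    }
    if (use_contours) {
      g2 <- grid; g2$phi <- phi
      tr <- hierarchical_transform(affine, g2)
      gi <- icp_phi_gradient(g2, tr, contours_ref, contours_target,
                             cost_config, alphas)
      garr[, , 1] <- garr[, , 1] + gi$gx
      garr[, , 2] <- garr[, , 2] + gi$gy
    }
    if (max(abs(garr)) == 0) { converged <- TRUE; break }
    step <- garr
    if (is.null(Hicp)) {
      step <- step * gain
    } else {
      a <- 1 / gain + Hicp$H11; b <- Hicp$H12; cc <- 1 / gain + Hicp$H22
      det <- a * cc - b^2
      step[, , 1] <- (cc * garr[, , 1] - b * garr[, , 2]) / det
      step[, , 2] <- (a * garr[, , 2] - b * garr[, , 1]) / det
    }
    smax <- max(abs(step))
    # trust region: the block preconditioner neglects the coupling between
    # neighbouring control points, so an unrestricted Newton-sized first
    # step can badly overshoot; no control point may move more than step0
    # per iteration
    q <- min(q, config$step0[1] / smax)
    repeat {
      prop <- phi - q * step
      cnew <- eval_cost(prop)
      if (is.finite(cnew["total"]) && cnew["total"] <= cur["total"]) break
      q <- q / 2
      if (q * smax < 1e-12) {
        if (!is.finite(cnew["total"]))
          stop("step underflow while rejecting non-finite cost steps")
        cnew <- cur; prop <- phi
        break
      }
    }
    decrease <- cur["total"] - cnew["total"]
    phi <- prop; cur <- cnew
    if (decrease > 0) q <- min(1.2 * q, 1)
    traj[[length(traj) + 1L]] <- c(it, cur["c_sim"], cur["c_icp"],
                                   cur["total"])
    if (cur["total"] < best["total"]) { best <- cur; best_phi <- phi }
    if (rel_tol) tol <- 1e-6 * abs(cur["total"])
    if (decrease < tol) { converged <- TRUE; break }
  }
  out <- grid
  out$phi <- best_phi
  tm <- do.call(rbind, traj)
  attr(out, "trajectory") <- tibble::tibble(iteration = tm[, 1],
                                            c_sim = tm[, 2],
                                            c_icp = tm[, 3],
                                            total = tm[, 4])
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "final_cost") <- best
  attr(out, "gain") <- gain
  out
}

#' Register one frame to the reference: global then local stage
#'
#' @inheritParams register_local
#' @param global_config optional [optimizer_config()] for the affine stage.
#' @param local_config optional [optimizer_config()] for the FFD stage.
#' @param warm_grid optional [ffd_grid()] initializing the local stage
#'   (e.g. from the previous frame's solution).
#' @param presmooth_sigma Gaussian pre-smoothing for both stages.
#' @param warm_affine optional [affine_params()]; when given, the global
#'   stage is skipped and this affine is used directly.
#' @return A [hierarchical_transform()] with diagnostics (`c_sim`, `c_icp`,
#'   per-stage iterations, cost trajectory) attached as attributes.
#' @export
register_frame <- function(reference, target,
                           contours_ref = NULL, contours_target = NULL,
                           global_config = NULL, local_config = NULL,
                           cost_config = lvstrain::cost_config(),
                           grid_spacing = 8,
                           warm_grid = NULL, warm_affine = NULL,
                           presmooth_sigma = 1) {
  affine <- if (is.null(warm_affine)) {
    register_global(reference, target, global_config, presmooth_sigma)
  } else warm_affine
  grid <- register_local(reference, target, affine,
                         contours_ref = contours_ref,
                         contours_target = contours_target,
                         config = local_config, cost_config = cost_config,
                         grid_spacing = grid_spacing, grid = warm_grid,
                         presmooth_sigma = presmooth_sigma)
  tr <- hierarchical_transform(affine, grid)
  attr(tr, "trajectory") <- attr(grid, "trajectory")
  attr(tr, "final_cost") <- attr(grid, "final_cost")
  attr(tr, "iterations") <- c(global = attr(affine, "iterations") %||% NA,
                              local = attr(grid, "iterations"))
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dense displacement field of a transform on the reference grid
#'
#' Evaluates the combined transform at every reference pixel and stores the
#' displacement (mapped minus original coordinate, pixels). The mask marks
#' pixels with full FFD support (all of them for lattices built with
#' [default_ffd_grid()]).
#'
#' @param transform a [hierarchical_transform()], or `NULL` for the
#'   identically-zero frame-0 field.
#' @param dim image dimension `c(nrow, ncol)`.
#' @param frame frame index the field belongs to.
#' @return An object of class `displacement_field`: list with `u`
#'   (`nrow x ncol x 2` array, x then y component), `frame`, `mask`.
#' @export
displacement_field <- function(transform, dim, frame = 0L) {
  u <- array(0, dim = c(dim[1], dim[2], 2L))
  mask <- matrix(TRUE, dim[1], dim[2])
  if (!is.null(transform)) {
    g <- pixel_grid(dim)
    pts <- cbind(as.numeric(g$x), as.numeric(g$y))
    mapped <- combined_apply(transform, pts)
    u[, , 1] <- matrix(mapped[, 1] - pts[, 1], dim[1], dim[2])
    u[, , 2] <- matrix(mapped[, 2] - pts[, 2], dim[1], dim[2])
  }
  structure(list(u = u, frame = as.integer(frame), mask = mask),
            class = "displacement_field")
}

#' Frame-to-reference displacement fields for a whole cine sequence
#'
#' Registers every frame directly against the reference frame (frame 0,
#' end-diastole) — never by accumulating consecutive pairwise registrations
#' — and converts each fitted transform to a dense displacement field on
#' the reference grid. The optional warm start initializes frame t's FFD
#' from frame t-1's solution purely as an initialization aid; the objective
#' always compares to frame 0.
#'
#' @param cine a [cine_sequence()].
#' @param contours optional nested contour list
#'   (`contours[[frame_id]][[label]]`, frame ids as characters, frame 0
#'   required) as returned by [read_contours_csv()] or the phantom
#'   generator.
#' @param cost_config a [cost_config()].
#' @param grid_spacing FFD control-point spacing in pixels.
#' @param global_config,local_config optional [optimizer_config()]s.
#' @param warm_start initialize each frame from the previous solution.
#' @param presmooth_sigma Gaussian pre-smoothing for both stages.
#' @return A list of class `displacement_sequence`: `fields` (one
#'   [displacement_field()] per frame), `transforms` (per-frame
#'   [hierarchical_transform()], `NULL` for frame 0), `failures`
#'   (per-frame error messages, if any).
#' @export
extract_displacement_sequence <- function(cine, contours = NULL,
                                          cost_config = lvstrain::cost_config(),
                                          grid_spacing = 8,
                                          global_config = NULL,
                                          local_config = NULL,
                                          warm_start = TRUE,
                                          presmooth_sigma = 1) {
  stopifnot(inherits(cine, "cine_sequence"))
  nF <- length(cine$frames)
  if (nF < 2L) stop("a cine sequence needs at least 2 frames")
  ref <- cine$frames[[1L]]
  dims <- dim(ref)
  fields <- vector("list", nF)
  transforms <- vector("list", nF)
  failures <- list()
  fields[[1L]] <- displacement_field(NULL, dims, frame = 0L)
  contours_ref <- if (!is.null(contours)) contours[["0"]] else NULL
  prev_grid <- NULL; prev_affine <- NULL
  for (t in seq_len(nF - 1L)) {
    tgt <- cine$frames[[t + 1L]]
    ct <- if (!is.null(contours)) contours[[as.character(t)]] else NULL
    res <- tryCatch({
      register_frame(ref, tgt,
                     contours_ref = contours_ref, contours_target = ct,
                     global_config = global_config,
                     local_config = local_config,
                     cost_config = cost_config,
                     grid_spacing = grid_spacing,
                     warm_grid = if (warm_start) prev_grid else NULL,
                     presmooth_sigma = presmooth_sigma)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(t)]] <- conditionMessage(res)
      next
    }
    transforms[[t + 1L]] <- res
    fields[[t + 1L]] <- displacement_field(res, dims, frame = t)
    if (warm_start)
      prev_grid <- ffd_grid(phi = res$grid$phi, delta = res$grid$delta,
                            origin = res$grid$origin)
  }
  if (length(failures))
    warning(sprintf("%d frame(s) failed to register: %s",
                    length(failures), paste(names(failures), collapse = ", ")))
  structure(list(fields = fields, transforms = transforms,
                 failures = failures,
                 pixel_spacing = cine$pixel_spacing,
                 frame_interval = cine$frame_interval),
            class = "displacement_sequence")
}
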