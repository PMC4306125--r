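#' Registration cost configuration
#'
#' @param lambda weight of the contour-correspondence penalty (>= 0);
#'   0 recovers the purely intensity-driven method. Can be raised for
#'   sequences with large deformation.
#' @param alpha1,alpha2 weights of the positional and curvature components
#'   of the matching distance; `NULL` means compute them from the data with
#'   [compute_alpha_weights()].
#' @param recompute_alpha_each_iteration recompute the alpha weights after
#'   every contour propagation instead of freezing the frame-0 values
#'   (default `FALSE`: frozen weights keep the objective stationary).
#' @param refresh_curvature recompute advected-contour curvatures after each
#'   propagation (default `TRUE`; deformation changes curvature).
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(lambda = 1, alpha1 = NULL, alpha2 = NULL,
                        recompute_alpha_each_iteration = FALSE,
                        refresh_curvature = TRUE) {
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (!is.null(alpha1) && alpha1 < 0) stop("'alpha1' must be non-negative")
  if (!is.null(alpha2) && alpha2 < 0) stop("'alpha2' must be non-negative")
  structure(list(lambda = lambda, alpha1 = alpha1, alpha2 = alpha2,
                 recompute_alpha_each_iteration =
                   isTRUE(recompute_alpha_each_iteration),
                 refresh_curvature = isTRUE(refresh_curvature)),
            class = "cost_config")
}

#' Mean sum-of-squared-differences image similarity
#'
#' \eqn{C_{sim} = (1/N) \sum (A - T(B))^2} over all N pixels, where
#' `warped_target` is the target frame resampled through the current
#' transform.
#'
#' @param reference,warped_target matrices of identical shape.
#' @return Scalar similarity cost (0 for identical images).
#' @export
ssd <- function(reference, warped_target) {
  if (!identical(dim(reference), dim(warped_target)))
    stop("images must have identical shapes")
  mean((reference - warped_target)^2)
}

#' Positional + curvature matching distance between contour points
#'
#' Distance between feature points \eqn{M_1=(x_1,y_1,k_1)} and
#' \eqn{M_2=(x_2,y_2,k_2)}:
#' \deqn{d = \alpha_1 [(x_1-x_2)^2 + (y_1-y_2)^2] + \alpha_2 (k_1-k_2)^2,}
#' a compromise of squared Euclidean and squared curvature-difference terms
#' (no outer square root).
#'
#' @param m1,m2 length-3 vectors (x, y, curvature).
#' @param alpha1,alpha2 non-negative component weights.
#' @return Scalar distance.
#' @export
feature_distance <- function(m1, m2, alpha1, alpha2) {
  stopifnot(alpha1 >= 0, alpha2 >= 0)
  alpha1 * ((m1[1] - m2[1])^2 + (m1[2] - m2[2])^2) +
    alpha2 * (m1[3] - m2[3])^2
}

pairwise_terms <- function(source, target) {
  sp <- source$points; tp <- target$points
  d2 <- outer(tp[, 1], sp[, 1], "-")^2 + outer(tp[, 2], sp[, 2], "-")^2
  k2 <- outer(target$curvatures, source$curvatures, "-")^2
  list(pos = d2, curv = k2) # rows = target points, cols = source points
}

#' Data-driven weights for the matching distance
#'
#' Each component weight is the reciprocal of the range (max minus min) of
#' its term over all source-target point pairs, so both components
#' contribute on comparable scales. A component with zero range carries no
#' information and gets weight 0 with a warning.
#'
#' @param source,target [contour_point_set()] objects.
#' @return Named numeric vector `c(alpha1, alpha2)`.
#' @export
compute_alpha_weights <- function(source, target) {
  tm <- pairwise_terms(source, target)
  # a component whose term barely varies across pairs cannot discriminate
  # between candidate matches (max ~ min, e.g. the curvature of two
  # concentric circles); its reciprocal weight would explode, so it is
  # treated like the zero-range case
  info_range <- function(m) {
    r <- max(m) - min(m)
    if (r <= 0 || r < 0.01 * max(m)) 0 else r
  }
  r1 <- info_range(tm$pos); r2 <- info_range(tm$curv)
  if (r1 <= 0) warning("degenerate positional range; alpha1 set to 0")
  if (r2 <= 0) warning("degenerate curvature range; alpha2 set to 0")
  c(alpha1 = if (r1 > 0) 1 / r1 else 0,
    alpha2 = if (r2 > 0) 1 / r2 else 0)
}

#' Closest-point correspondences with curvature as an invariant feature
#'
#' For every point of the moving (`target_current`) set, finds the source
#' point minimizing [feature_distance()] by exhaustive search (contour sets
#' are at most a few hundred points). With `alpha2 = 0` this is plain
#' nearest-neighbour Euclidean matching.
#'
#' @param source static candidate [contour_point_set()] (closest points are
#'   drawn from it).
#' @param target_current current moving [contour_point_set()].
#' @param alpha1,alpha2 matching-distance weights.
#' @return An object of class `correspondence_set` with elements `target`
#'   (the moving set), `source`, `match_index` (into the source points),
#'   `distances` (per-pair matching distance) and the weights used.
#' @export
icpif_match <- function(source, target_current, alpha1, alpha2) {
  stopifnot(inherits(source, "contour_point_set"),
            inherits(target_current, "contour_point_set"))
  if (nrow(source$points) == 0L || nrow(target_current$points) == 0L)
    stop("contour point sets must be non-empty")
  tm <- pairwise_terms(source, target_current)
  D <- alpha1 * tm$pos + alpha2 * tm$curv
  idx <- max.col(-D, ties.method = "first")
  structure(list(target = target_current, source = source,
                 match_index = idx,
                 distances = D[cbind(seq_along(idx), idx)],
                 alpha1 = alpha1, alpha2 = alpha2),
            class = "correspondence_set")
}

#' Contour correspondence penalty
#'
#' The sum (not the mean) of the matching distances over all matched pairs,
#' so the penalty grows with contour sampling density.
#'
#' @param matches a `correspondence_set` from [icpif_match()].
#' @param alpha1,alpha2 weights; default to those stored in `matches`.
#' @return Scalar penalty (0 for perfectly matched sets).
#' @export
c_icp <- function(matches, alpha1 = NULL, alpha2 = NULL) {
  stopifnot(inherits(matches, "correspondence_set"))
  if (is.null(alpha1) && is.null(alpha2)) return(sum(matches$distances))
  a1 <- if (is.null(alpha1)) matches$alpha1 else alpha1
  a2 <- if (is.null(alpha2)) matches$alpha2 else alpha2
  q <- matches$source$points[matches$match_index, , drop = FALSE]
  qk <- matches$source$curvatures[matches$match_index]
  p <- matches$target$points
  sum(a1 * ((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2) +
        a2 * (matches$target$curvatures - qk)^2)
}

# Advect a contour through a hierarchical transform; optionally recompute
# curvature on the deformed polygon (deformation changes curvature).
propagate_contour <- function(contour, transform, refresh_curvature = TRUE) {
  p <- combined_apply(transform, contour$points)
  if (refresh_curvature)
    contour_point_set(p, label = contour$label, closed = contour$closed)
  else
    contour_point_set(p, label = contour$label, closed = contour$closed,
                      curvatures = contour$curvatures)
}

# Contour part of the registration objective for a given transform:
# reference contours move with the mesh into the target frame and are
# matched against the target-frame contour sets.
contour_penalty <- function(transform, contours_ref, contours_target,
                            config, alphas) {
  total <- 0
  details <- list()
  for (lb in names(contours_ref)) {
    if (is.null(contours_target[[lb]])) next
    moved <- propagate_contour(contours_ref[[lb]], transform,
                               config$refresh_curvature)
    a <- alphas[[lb]]
    if (config$recompute_alpha_each_iteration)
      a <- suppressWarnings(
        compute_alpha_weights(contours_target[[lb]], moved))
    m <- icpif_match(contours_target[[lb]], moved, a[1], a[2])
    total <- total + c_icp(m)
    details[[lb]] <- m
  }
  list(value = total, matches = details)
}

#' Total registration cost
#'
#' \eqn{Cost = C_{sim} + \lambda\, C_{ICP}}: the mean-SSD similarity of the
#' reference frame against the transform-resampled target, plus the
#' weighted contour correspondence penalty. The reference contours are
#' advected by the current transform (they move with the control-point
#' mesh) and matched against the target-frame contours; with `lambda = 0`
#' or absent contours the cost reduces exactly to the SSD.
#'
#' @param reference,target image matrices (identical shape).
#' @param transform a [hierarchical_transform()].
#' @param contours_ref named list of reference-frame [contour_point_set()]
#'   objects (e.g. `list(endo = ..., epi = ...)`), or `NULL`.
#' @param contours_target named list of target-frame contours, or `NULL`.
#' @param config a [cost_config()].
#' @param target_coef optional precomputed spline coefficients of `target`
#'   (from [spline_coefficients()]) to avoid refiltering.
#' @return Scalar cost, with attributes `c_sim` and `c_icp`.
#' @export
total_cost <- function(reference, target, transform,
                       contours_ref = NULL, contours_target = NULL,
                       config = cost_config(), target_coef = NULL) {
  stopifnot(inherits(config, "cost_config"))
  if (is.null(target_coef)) target_coef <- spline_coefficients(target)
  co <- warp_coords(transform, dim(reference))
  warped <- resample(target, co, coef = target_coef)
  csim <- ssd(reference, warped)
  cicp <- 0
  if (config$lambda > 0 && !is.null(contours_ref) &&
      !is.null(contours_target) && length(contours_ref)) {
    alphas <- lapply(names(contours_ref), function(lb) {
      a1 <- config$alpha1; a2 <- config$alpha2
      if (is.null(a1) || is.null(a2)) {
        a <- suppressWarnings(
          compute_alpha_weights(contours_target[[lb]], contours_ref[[lb]]))
        c(if (is.null(a1)) a[1] else a1, if (is.null(a2)) a[2] else a2)
      } else c(a1, a2)
    })
    names(alphas) <- names(contours_ref)
    cicp <- contour_penalty(transform, contours_ref, contours_target,
                            config, alphas)$value
  }
  structure(csim + config$lambda * cicp, c_sim = csim, c_icp = cicp)
}
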