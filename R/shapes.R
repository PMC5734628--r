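# Geometric primitives for continuous-domain phantom scenes.
#
# Every shape carries a centre (mm), an orientation matrix Q (world =
# Q %*% local + centre) and type-specific size parameters. Shapes expose
# three generic operations used by the voxelizer:
#   shape_contains(shape, pts)  - indicator at world points (n x 3 matrix)
#   shape_classify(shape, pts, h) - -1 surely outside / +1 surely inside /
#       0 possibly straddling, for points that are voxel centres of voxels
#       with half-diagonal h (conservative bounds, exact for spheres)
#   shape_bbox(shape) - world axis-aligned bounding box (2 x 3)

#' Shape primitives
#'
#' Constructors for the geometric primitives used in phantom scenes:
#' spheres, ellipsoids, axis-oriented boxes and elliptical cylinders.
#' Dimensions are in mm; `orientation` is a 3x3 rotation matrix mapping
#' local to world axes.
#'
#' @param center world centre, mm (length 3).
#' @param diameter sphere diameter, mm (> 0).
#' @param semi_axes ellipsoid semi-axis lengths, mm (length 3, > 0).
#' @param half_sizes box half edge lengths, mm (length 3, > 0).
#' @param semi_axis_a,semi_axis_b cylinder cross-section semi-axes, mm.
#' @param half_length cylinder half length along its local z axis, mm.
#' @param orientation 3x3 rotation matrix (default identity).
#' @return A shape object (classes `shape` plus the specific type).
#' @name shapes
NULL

new_shape <- function(type, center, orientation, extra) {
  center <- as.numeric(rep_len(center, 3L))
  if (!is.matrix(orientation) || any(dim(orientation) != c(3L, 3L)))
    stop("orientation must be a 3x3 matrix")
  structure(c(list(type = type, center = center, orientation = orientation), extra),
            class = c(paste0("shape_", type), "shape"))
}

#' @rdname shapes
#' @export
sphere_shape <- function(center, diameter) {
  if (!is.finite(diameter) || diameter <= 0) stop("sphere diameter must be > 0")
  new_shape("sphere", center, diag(3), list(radius = diameter / 2))
}

#' @rdname shapes
#' @export
ellipsoid_shape <- function(center, semi_axes, orientation = diag(3)) {
  semi_axes <- as.numeric(rep_len(semi_axes, 3L))
  if (any(semi_axes <= 0)) stop("ellipsoid semi-axes must be > 0")
  new_shape("ellipsoid", center, orientation, list(semi_axes = semi_axes))
}

#' @rdname shapes
#' @export
box_shape <- function(center, half_sizes, orientation = diag(3)) {
  half_sizes <- as.numeric(rep_len(half_sizes, 3L))
  if (any(half_sizes <= 0)) stop("box half sizes must be > 0")
  new_shape("box", center, orientation, list(half_sizes = half_sizes))
}

#' @rdname shapes
#' @export
ecylinder_shape <- function(center, semi_axis_a, semi_axis_b, half_length,
                            orientation = diag(3)) {
  if (semi_axis_a <= 0 || semi_axis_b <= 0 || half_length <= 0)
    stop("cylinder dimensions must be > 0")
  new_shape("ecylinder", center, orientation,
            list(semi_axes = c(semi_axis_a, semi_axis_b), half_length = half_length))
}

#' Analytic shape volume in cubic mm
#' @param shape a shape object.
#' @export
shape_volume_mm3 <- function(shape) {
  switch(shape$type,
    sphere = 4 / 3 * pi * shape$radius^3,
    ellipsoid = 4 / 3 * pi * prod(shape$semi_axes),
    box = 8 * prod(shape$half_sizes),
    ecylinder = pi * prod(shape$semi_axes) * 2 * shape$half_length,
    stop("unknown shape type"))
}

to_local <- function(shape, pts) {
  sweep(pts, 2, shape$center) %*% shape$orientation  # pts %*% Q == t(Q^T %*% p)
}

#' Point-in-shape test
#' @param shape a shape object.
#' @param pts n x 3 matrix of world points (mm).
#' @return logical vector of length n.
#' @export
shape_contains <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  q <- to_local(shape, pts)
  switch(shape$type,
    sphere = rowSums(q^2) <= shape$radius^2,
    ellipsoid = {
      u <- sweep(q, 2, shape$semi_axes, "/")
      rowSums(u^2) <= 1
    },
    box = {
      u <- abs(q)
      u[, 1] <= shape$half_sizes[1] & u[, 2] <= shape$half_sizes[2] &
        u[, 3] <= shape$half_sizes[3]
    },
    ecylinder = {
      rho2 <- (q[, 1] / shape$semi_axes[1])^2 + (q[, 2] / shape$semi_axes[2])^2
      rho2 <= 1 & abs(q[, 3]) <= shape$half_length
    },
    stop("unknown shape type"))
}

# Conservative three-way classification of voxels by centre point.
# h is the voxel half-diagonal (mm). Returns -1 / 0 / +1.
shape_classify <- function(shape, pts, h) {
  q <- to_local(shape, pts)
  out <- integer(nrow(q))
  switch(shape$type,
    sphere = {
      d <- sqrt(rowSums(q^2))
      out[d <= shape$radius - h] <- 1L
      out[d >= shape$radius + h] <- -1L
    },
    ellipsoid = {
      u <- sqrt(rowSums(sweep(q, 2, shape$semi_axes, "/")^2))
      m <- h / min(shape$semi_axes)
      out[u <= 1 - m] <- 1L
      out[u >= 1 + m] <- -1L
    },
    box = {
      u <- abs(q)
      ins <- u[, 1] <= shape$half_sizes[1] - h & u[, 2] <= shape$half_sizes[2] - h &
        u[, 3] <= shape$half_sizes[3] - h
      outs <- u[, 1] >= shape$half_sizes[1] + h | u[, 2] >= shape$half_sizes[2] + h |
        u[, 3] >= shape$half_sizes[3] + h
      out[ins] <- 1L
      out[outs] <- -1L
    },
    ecylinder = {
      rho <- sqrt((q[, 1] / shape$semi_axes[1])^2 + (q[, 2] / shape$semi_axes[2])^2)
      m <- h / min(shape$semi_axes)
      z <- abs(q[, 3])
      ins <- rho <= 1 - m & z <= shape$half_length - h
      outs <- rho >= 1 + m | z >= shape$half_length + h
      out[ins] <- 1L
      out[outs] <- -1L
    },
    stop("unknown shape type"))
  out
}

shape_bbox <- function(shape) {
  # reach of the oriented shape along each world axis
  Q <- shape$orientation
  reach <- switch(shape$type,
    sphere = rep(shape$radius, 3),
    ellipsoid = sqrt((Q^2 %*% shape$semi_axes^2)[, 1]),
    box = (abs(Q) %*% shape$half_sizes)[, 1],
    ecylinder = {
      half <- c(shape$semi_axes, shape$half_length)
      sqrt((Q[, 1:2]^2 %*% shape$semi_axes^2)[, 1]) + abs(Q[, 3]) * shape$half_length
    },
    stop("unknown shape type"))
  rbind(lower = shape$center - reach, upper = shape$center + reach)
}

shape_to_list <- function(shape) {
  lst <- unclass(shape)
  lst$orientation <- as.vector(lst$orientation)
  lst
}

shape_from_list <- function(lst) {
  Q <- matrix(as.numeric(lst$orientation), 3, 3)
  switch(lst$type,
    sphere = { s <- sphere_shape(as.numeric(lst$center), 2 * as.numeric(lst$radius)); s$orientation <- Q; s },
    ellipsoid = ellipsoid_shape(as.numeric(lst$center), as.numeric(lst$semi_axes), Q),
    box = box_shape(as.numeric(lst$center), as.numeric(lst$half_sizes), Q),
    ecylinder = ecylinder_shape(as.numeric(lst$center), as.numeric(lst$semi_axes)[1],
                                as.numeric(lst$semi_axes)[2], as.numeric(lst$half_length), Q),
    stop("unknown shape type"))
}
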