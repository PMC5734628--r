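#' Rigid transforms for phantom repositioning
#'
#' A rigid transform rotates about the world origin (phantom scenes are
#' built centred on the origin) and then translates:
#' `p' = R p + t`, with `R = Rz Ry Rx` built from per-axis Euler angles in
#' degrees.
#'
#' @param rotation_deg Euler angles (x, y, z) in degrees.
#' @param translation_mm translation vector, mm.
#' @return An object of class `rigid_transform` carrying the rotation
#'   matrix alongside the angles.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0), translation_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rep_len(rotation_deg, 3L))
  translation_mm <- as.numeric(rep_len(translation_mm, 3L))
  if (any(!is.finite(rotation_deg)) || any(!is.finite(translation_mm)))
    stop("transform parameters must be finite")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 matrix = euler_matrix(rotation_deg)),
            class = "rigid_transform")
}

euler_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.3g, %.3g, %.3g) deg, trans (%.3g, %.3g, %.3g) mm\n",
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]))
  invisible(x)
}

#' Draw a random repositioning transform
#'
#' Per-axis rotation angles are uniform on `[-max_rotation_deg,
#' +max_rotation_deg]` and the translation is uniform in the ball of
#' radius `max_displacement_mm`, matching repositioning protocols that
#' bound per-axis tilt (< 5 degrees) and total displacement (up to
#' 20 mm).
#'
#' @param max_rotation_deg per-axis rotation bound, degrees (>= 0).
#' @param max_displacement_mm displacement bound, mm (>= 0).
#' @param seed optional integer; if given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @export
sample_transform <- function(max_rotation_deg, max_displacement_mm, seed = NULL) {
  if (max_rotation_deg < 0 || max_displacement_mm < 0)
    stop("repositioning bounds must be >= 0")
  draw <- function() {
    ang <- stats::runif(3, -max_rotation_deg, max_rotation_deg)
    if (max_displacement_mm > 0) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      t <- dir * max_displacement_mm * stats::runif(1)^(1 / 3)
    } else t <- c(0, 0, 0)
    rigid_transform(ang, t)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Apply, compose and invert rigid transforms
#'
#' `transform_points()` maps world points; `apply_transform()` moves every
#' compartment of a scene rigidly (centres and orientations transformed,
#' concentrations untouched) so no interpolation is involved;
#' `invert_transform()` returns the exact group inverse.
#'
#' @param t,transform a [rigid_transform()].
#' @param pts n x 3 matrix of world points.
#' @param sc a [scene()].
#' @name transform-ops
#' @export
transform_points <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(t$matrix), 2, t$translation_mm, "+")
}

#' @rdname transform-ops
#' @export
invert_transform <- function(t) {
  inv <- rigid_transform()
  inv$matrix <- t(t$matrix)
  # Euler angles of the inverse are not the negated angles in general;
  # the matrix is authoritative, angles are kept only for reporting
  inv$rotation_deg <- c(NA_real_, NA_real_, NA_real_)
  inv$translation_mm <- as.numeric(-inv$matrix %*% t$translation_mm)
  inv
}

#' @rdname transform-ops
#' @export
compose_transforms <- function(t, transform) {
  out <- rigid_transform(c(0, 0, 0), c(0, 0, 0))
  out$matrix <- t$matrix %*% transform$matrix
  out$rotation_deg <- c(NA_real_, NA_real_, NA_real_)
  out$translation_mm <- as.numeric(t$matrix %*% transform$translation_mm) + t$translation_mm
  out
}

#' @rdname transform-ops
#' @export
apply_transform <- function(sc, t) {
  comps <- lapply(sc$compartments, function(cp) {
    s <- cp$shape
    s$center <- as.numeric(t$matrix %*% s$center + t$translation_mm)
    s$orientation <- t$matrix %*% s$orientation
    cp$shape <- s
    cp
  })
  meta <- sc$meta
  if (!is.null(meta$sphere_centers))
    meta$sphere_centers <- transform_points(t, meta$sphere_centers)
  meta$applied_transform <- t
  boxes <- lapply(comps, function(cp) shape_bbox(cp$shape))
  bb <- rbind(lower = do.call(pmin, lapply(boxes, function(b) b[1, ])),
              upper = do.call(pmax, lapply(boxes, function(b) b[2, ])))
  scene(comps, bounding_box = bb, meta = meta)
}

#' Identity transform predicate
#' @param t a [rigid_transform()].
#' @export
is_identity_transform <- function(t) {
  max(abs(t$matrix - diag(3))) < 1e-12 && all(abs(t$translation_mm) < 1e-12)
}
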