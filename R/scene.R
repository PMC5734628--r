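#' Construct a continuous-domain phantom scene
#'
#' A scene is an ordered list of compartments, each a shape primitive with
#' a true activity concentration in kBq/mL, over a zero-activity exterior.
#' Compartments are composited in painter's order: at any world point the
#' concentration is that of the last compartment containing the point.
#' Nested compartments (spheres inside a background vessel, white matter
#' inside a cortical shell) are therefore expressed by listing the inner
#' compartment after the outer one.
#'
#' @param compartments list of elements `list(shape =, concentration =,
#'   name =)`; concentrations must be finite and >= 0.
#' @param bounding_box optional 2 x 3 matrix (rows lower/upper, mm). If
#'   omitted, the union of compartment bounding boxes is used.
#' @param meta named list of free-form scene metadata (true concentrations,
#'   sphere diameters, ...), carried through transforms.
#' @return An object of class `scene`.
#' @export
scene <- function(compartments, bounding_box = NULL, meta = list()) {
  for (cp in compartments) {
    if (!inherits(cp$shape, "shape")) stop("each compartment needs a shape")
    if (!is.finite(cp$concentration) || cp$concentration < 0)
      stop("compartment concentrations must be finite and >= 0")
  }
  if (is.null(bounding_box)) {
    boxes <- lapply(compartments, function(cp) shape_bbox(cp$shape))
    bounding_box <- rbind(
      lower = do.call(pmin, lapply(boxes, function(b) b[1, ])),
      upper = do.call(pmax, lapply(boxes, function(b) b[2, ])))
  }
  structure(list(compartments = compartments, bounding_box = bounding_box,
                 meta = meta),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d compartments\n", length(x$compartments)))
  for (cp in x$compartments)
    cat(sprintf("  %-18s %-10s %.4g kBq/mL\n",
                if (is.null(cp$name)) "(unnamed)" else cp$name,
                cp$shape$type, cp$concentration))
  invisible(x)
}

#' Evaluate true scene concentration at world points
#'
#' @param sc a [scene()].
#' @param pts n x 3 matrix of world points (mm).
#' @return numeric vector of concentrations (kBq/mL); 0 outside all
#'   compartments.
#' @export
scene_concentration_at <- function(sc, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  vals <- numeric(nrow(pts))
  for (cp in sc$compartments) {
    inside <- shape_contains(cp$shape, pts)
    vals[inside] <- cp$concentration
  }
  vals
}

# Standard NEMA IQ sphere inner diameters (mm) and ring geometry.
NEMA_SPHERE_DIAMETERS <- c(10, 13, 17, 22, 28, 37)
NEMA_RING_RADIUS <- 57.2  # sphere centres, mm from phantom axis

#' Sphere centres of the NEMA IQ arrangement
#'
#' The six spheres sit coplanarly on a ring of radius 57.2 mm about the
#' phantom axis, 60 degrees apart, with the smallest sphere at the
#' 12-o'clock position and diameters increasing clockwise.
#'
#' @param ring_radius ring radius in mm.
#' @return 6 x 3 matrix of centres (mm), one row per diameter in
#'   increasing order 10..37 mm.
#' @export
iq_sphere_centers <- function(ring_radius = NEMA_RING_RADIUS) {
  ang <- pi / 2 - (0:5) * pi / 3
  cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
}

#' Build the digital NEMA IQ phantom scene
#'
#' Six fillable spheres of inner diameters 10, 13, 17, 22, 28 and 37 mm on
#' the standard 57.2 mm ring, inside a background vessel modelled as an
#' elliptical cylinder scaled to the 9400 mL background volume. Filling
#' the spheres and background at a 10:1 concentration ratio reproduces the
#' EANM/EARL filling scheme.
#'
#' @param sphere_concentration true sphere concentration, kBq/mL (> 0).
#' @param background_concentration true background concentration, kBq/mL
#'   (> 0).
#' @return A [scene()] whose `meta` records the true concentrations,
#'   sphere diameters and centres.
#' @export
build_iq_scene <- function(sphere_concentration, background_concentration) {
  if (!is.finite(sphere_concentration) || sphere_concentration <= 0)
    stop("sphere_concentration must be > 0")
  if (!is.finite(background_concentration) || background_concentration <= 0)
    stop("background_concentration must be > 0")
  # elliptical cylinder: semi-axes of the body-sized cross-section; length
  # chosen so that pi*a*b*L = 9400 mL
  a <- 147; b <- 106
  len <- 9400e3 / (pi * a * b)
  bg <- ecylinder_shape(c(0, 0, 0), a, b, len / 2)
  centers <- iq_sphere_centers()
  comps <- list(list(shape = bg, concentration = background_concentration,
                     name = "background"))
  for (i in seq_along(NEMA_SPHERE_DIAMETERS)) {
    comps[[i + 1L]] <- list(
      shape = sphere_shape(centers[i, ], NEMA_SPHERE_DIAMETERS[i]),
      concentration = sphere_concentration,
      name = sprintf("sphere_%dmm", NEMA_SPHERE_DIAMETERS[i]))
  }
  scene(comps,
        meta = list(phantom = "iq",
                    sphere_concentration = sphere_concentration,
                    background_concentration = background_concentration,
                    sphere_diameters = NEMA_SPHERE_DIAMETERS,
                    sphere_centers = centers))
}

#' Single-sphere sub-scene of the IQ phantom
#'
#' A compact scene containing one sphere in uniform background, used for
#' windowed replicate studies of a single sphere where simulating the full
#' 9400 mL vessel adds nothing (the sphere only interacts with nearby
#' background).
#'
#' @param diameter sphere diameter, mm.
#' @param sphere_concentration,background_concentration kBq/mL.
#' @param half_extent half edge of the cubic background region, mm;
#'   defaults to the sphere radius plus 60 mm.
#' @export
build_sphere_scene <- function(diameter, sphere_concentration,
                               background_concentration,
                               half_extent = diameter / 2 + 60) {
  if (!is.finite(sphere_concentration) || sphere_concentration <= 0)
    stop("sphere_concentration must be > 0")
  if (!is.finite(background_concentration) || background_concentration < 0)
    stop("background_concentration must be >= 0")
  comps <- list(
    list(shape = box_shape(c(0, 0, 0), rep(half_extent, 3)),
         concentration = background_concentration, name = "background"),
    list(shape = sphere_shape(c(0, 0, 0), diameter),
         concentration = sphere_concentration,
         name = sprintf("sphere_%gmm", diameter)))
  scene(comps,
        meta = list(phantom = "iq_single",
                    sphere_concentration = sphere_concentration,
                    background_concentration = background_concentration,
                    sphere_diameters = diameter,
                    sphere_centers = matrix(0, 1, 3)))
}

# Fractional coverage of one shape on a grid: bulk voxels classified by a
# conservative inside/outside test, only boundary voxels sampled at
# supersampling^3 subpoints.
shape_coverage <- function(shape, grid, supersampling) {
  d <- grid$dim
  vs <- grid$voxel_size
  h <- sqrt(sum((vs / 2)^2))
  bbox <- shape_bbox(shape)
  i0 <- pmax(floor((bbox[1, ] - grid$origin) / vs), 0)
  i1 <- pmin(ceiling((bbox[2, ] - grid$origin) / vs), d)
  if (any(i1 <= i0)) return(NULL)
  sub_dim <- as.integer(i1 - i0)
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq.int(i0[a] + 1L, i1[a]) - 0.5) * vs[a])
  n_sub <- prod(sub_dim)
  pts <- cbind(rep(ax[[1]], times = sub_dim[2] * sub_dim[3]),
               rep(rep(ax[[2]], each = sub_dim[1]), times = sub_dim[3]),
               rep(ax[[3]], each = sub_dim[1] * sub_dim[2]))
  cls <- shape_classify(shape, pts, h)
  frac <- numeric(n_sub)
  frac[cls == 1L] <- 1
  bnd <- which(cls == 0L)
  if (length(bnd)) {
    s <- as.integer(supersampling)
    offs1 <- ((seq_len(s) - 0.5) / s - 0.5)
    so <- as.matrix(expand.grid(offs1 * vs[1], offs1 * vs[2], offs1 * vs[3]))
    # chunk to bound memory: each chunk is (chunk x s^3) x 3 points
    chunk <- max(1L, as.integer(2e6 / nrow(so)))
    for (start in seq(1L, length(bnd), by = chunk)) {
      idx <- bnd[start:min(start + chunk - 1L, length(bnd))]
      base <- pts[idx, , drop = FALSE]
      n <- length(idx)
      p <- cbind(rep(base[, 1], each = nrow(so)) + rep(so[, 1], times = n),
                 rep(base[, 2], each = nrow(so)) + rep(so[, 2], times = n),
                 rep(base[, 3], each = nrow(so)) + rep(so[, 3], times = n))
      ins <- shape_contains(shape, p)
      frac[idx] <- colMeans(matrix(ins, nrow = nrow(so)))
    }
  }
  list(index0 = as.integer(i0), dim = sub_dim, frac = frac)
}

#' Voxelize a scene with fractional voxel coverage
#'
#' Rasterizes a continuous-domain scene onto a voxel grid. Each voxel's
#' value is the volume-weighted average concentration over
#' `supersampling^3` subvoxel sample points (evaluated only for voxels
#' straddling a compartment boundary; voxels provably interior or exterior
#' to every compartment are filled analytically). Compositing follows the
#' scene's painter order. The result is deterministic for fixed inputs.
#'
#' @param sc a [scene()].
#' @param grid a [grid_spec()]; must cover the scene bounding box
#'   (checked with `check_coverage`).
#' @param supersampling subvoxel samples per axis (integer >= 1,
#'   default 4).
#' @param check_coverage error if the grid does not contain the scene
#'   bounding box (default TRUE; windowed simulations of a sub-region set
#'   this to FALSE deliberately).
#' @return An [activity_image()].
#' @export
voxelize_scene <- function(sc, grid, supersampling = 4L, check_coverage = TRUE) {
  if (supersampling < 1L) stop("supersampling must be >= 1")
  if (check_coverage) {
    ext <- grid_extent(grid)
    tol <- 1e-9
    if (any(sc$bounding_box[1, ] < ext[1, ] - tol) ||
        any(sc$bounding_box[2, ] > ext[2, ] + tol))
      stop("grid does not cover the scene bounding region")
  }
  vals <- array(0, dim = grid$dim)
  for (cp in sc$compartments) {
    cov <- shape_coverage(cp$shape, grid, supersampling)
    if (is.null(cov)) next
    ix <- seq.int(cov$index0[1] + 1L, cov$index0[1] + cov$dim[1])
    iy <- seq.int(cov$index0[2] + 1L, cov$index0[2] + cov$dim[2])
    iz <- seq.int(cov$index0[3] + 1L, cov$index0[3] + cov$dim[3])
    f <- array(cov$frac, dim = cov$dim)
    vals[ix, iy, iz] <- vals[ix, iy, iz] * (1 - f) + cp$concentration * f
  }
  activity_image(vals, grid,
                 provenance = list(voxelize = list(supersampling = as.integer(supersampling))))
}

#' Serialize scenes to and from JSON
#'
#' @param sc a [scene()].
#' @param path file path; for `scene_to_json` with `path = NULL` the JSON
#'   string is returned.
#' @name scene-json
#' @export
scene_to_json <- function(sc, path = NULL) {
  obj <- list(compartments = lapply(sc$compartments, function(cp)
                list(name = cp$name, concentration = cp$concentration,
                     shape = shape_to_list(cp$shape))),
              bounding_box = as.vector(sc$bounding_box),
              meta = sc$meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname scene-json
#' @export
scene_from_json <- function(path) {
  obj <- jsonlite::fromJSON(if (file.exists(path)) paste(readLines(path), collapse = "")
                            else path, simplifyVector = FALSE)
  comps <- lapply(obj$compartments, function(cp)
    list(shape = shape_from_list(cp$shape),
         concentration = as.numeric(cp$concentration),
         name = cp$name))
  meta <- lapply(obj$meta, function(x)
    if (is.list(x)) do.call(rbind, lapply(x, unlist)) else unlist(x))
  bb <- matrix(as.numeric(unlist(obj$bounding_box)), 2, 3)
  rownames(bb) <- c("lower", "upper")
  scene(comps, bounding_box = bb, meta = meta)
}
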