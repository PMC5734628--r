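#' Build a 1 mL spherical peak kernel with fractional voxel coverage
#'
#' Weights are the fractional overlap of each voxel with a sphere of
#' volume `volume_mL` (radius `(3V / 4 pi)^(1/3)`, 6.2035 mm for 1 mL)
#' centred on a voxel centre, computed by subvoxel counting. The weighted
#' voxel volume sums to the nominal VOI volume, so peak averages account
#' for fractional voxel coverage on coarse grids.
#'
#' @param grid a [grid_spec()]; only voxel sizes are used.
#' @param volume_mL VOI volume in mL (default 1).
#' @param supersampling subvoxel samples per axis for the coverage
#'   fractions (default 8).
#' @return An object of class `peak_kernel` with integer `offsets`
#'   (n x 3, voxel steps from the candidate centre) and `weights` in
#'   `[0, 1]`.
#' @export
make_peak_kernel <- function(grid, volume_mL = 1, supersampling = 8L) {
  if (!is.finite(volume_mL) || volume_mL <= 0) stop("volume_mL must be > 0")
  vs <- grid$voxel_size
  radius <- (3 * volume_mL * 1000 / (4 * pi))^(1 / 3)
  if (any(vs > 2 * radius))
    stop("voxel larger than the peak VOI diameter: kernel degenerate")
  r_vox <- as.integer(ceiling(radius / vs + 0.5))
  offs <- as.matrix(expand.grid(x = -r_vox[1]:r_vox[1],
                                y = -r_vox[2]:r_vox[2],
                                z = -r_vox[3]:r_vox[3]))
  pts <- sweep(offs, 2, vs, "*")
  h <- sqrt(sum((vs / 2)^2))
  sph <- sphere_shape(c(0, 0, 0), 2 * radius)
  cls <- shape_classify(sph, pts, h)
  w <- numeric(nrow(offs))
  w[cls == 1L] <- 1
  bnd <- which(cls == 0L)
  if (length(bnd)) {
    s <- as.integer(supersampling)
    offs1 <- ((seq_len(s) - 0.5) / s - 0.5)
    so <- as.matrix(expand.grid(offs1 * vs[1], offs1 * vs[2], offs1 * vs[3]))
    for (i in bnd) {
      p <- sweep(so, 2, pts[i, ], "+")
      w[i] <- mean(rowSums(p^2) <= radius^2)
    }
  }
  keep <- w > 0
  structure(list(offsets = offs[keep, , drop = FALSE], weights = w[keep],
                 radius_mm = radius, volume_mL = volume_mL,
                 voxel_size = vs),
            class = "peak_kernel")
}

#' Volume represented by a peak kernel
#'
#' Sum of kernel weights times the voxel volume, in mL; should equal the
#' nominal VOI volume to within the subvoxel-counting tolerance.
#'
#' @param kernel a [make_peak_kernel()] result.
#' @export
peak_kernel_volume_mL <- function(kernel) {
  sum(kernel$weights) * prod(kernel$voxel_size) / 1000
}

region_to_mask <- function(image, region) {
  if (is.logical(region)) {
    if (!all(dim(region) == dim(image$values)))
      stop("search region dimensions do not match image")
    return(region)
  }
  stop("search region must be a logical array")
}

#' Maximum-voxel uptake (SUVmax)
#'
#' Maximum voxel value inside a search region; ties are broken by the
#' lowest linear index.
#'
#' @param image an [activity_image()].
#' @param search_region logical array matching the image dimensions.
#' @return list with `value` and `index` (1-based array index).
#' @export
suv_max <- function(image, search_region) {
  mask <- region_to_mask(image, search_region)
  idx <- which(mask)
  if (!length(idx)) stop("empty search region")
  vals <- image$values[idx]
  k <- which.max(vals)
  list(value = vals[k],
       index = arrayInd(idx[k], dim(image$values))[1, ])
}

#' Peak uptake over a 1 mL spherical VOI search (SUVpeak)
#'
#' Exhaustively evaluates the kernel-weighted mean at every voxel-centre
#' candidate inside the search region (subvoxel centre offsets are not
#' searched) and returns the highest average. Candidates where the kernel
#' would extend outside the image are excluded.
#'
#' @param image an [activity_image()].
#' @param kernel a [make_peak_kernel()] built on the same voxel size.
#' @param search_region logical array of candidate centre voxels.
#' @return list with `value` and `index` of the best centre.
#' @export
suv_peak <- function(image, kernel, search_region) {
  if (max(abs(kernel$voxel_size - image$grid$voxel_size)) > 1e-6)
    stop("kernel voxel size does not match image grid")
  mask <- region_to_mask(image, search_region)
  d <- dim(image$values)
  lo <- -apply(kernel$offsets, 2, min)
  hi <- apply(kernel$offsets, 2, max)
  cand <- which(mask)
  ai <- arrayInd(cand, d)
  ok <- ai[, 1] > lo[1] & ai[, 1] <= d[1] - hi[1] &
        ai[, 2] > lo[2] & ai[, 2] <= d[2] - hi[2] &
        ai[, 3] > lo[3] & ai[, 3] <= d[3] - hi[3]
  cand <- cand[ok]
  if (!length(cand)) stop("peak kernel does not fit inside the image at any candidate")
  lin_off <- kernel$offsets[, 1] + kernel$offsets[, 2] * d[1] +
    kernel$offsets[, 3] * d[1] * d[2]
  acc <- numeric(length(cand))
  v <- as.vector(image$values)
  for (j in seq_along(lin_off))
    acc <- acc + kernel$weights[j] * v[cand + lin_off[j]]
  acc <- acc / sum(kernel$weights)
  k <- which.max(acc)
  list(value = acc[k], index = arrayInd(cand[k], d)[1, ])
}

NEIGHBORS_26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, ]
})

#' Background-corrected 50% isocontour segmentation (A50)
#'
#' Finds the local maximum near a supplied approximate centre, thresholds
#' at `T = B + 0.5 (SUVmax_local - B)` where `B` is the background
#' estimate, and keeps the largest 26-connected component of voxels with
#' value >= T that contains the local-maximum voxel.
#'
#' @param image an [activity_image()].
#' @param center approximate world centre of the object, mm.
#' @param background_estimate background concentration `B`, kBq/mL
#'   (>= 0).
#' @param search_radius radius (mm) around `center` in which the local
#'   maximum is sought.
#' @return list with logical `mask`, `threshold`, `local_max`,
#'   `volume_mL` and the seed `index`.
#' @export
segment_a50 <- function(image, center, background_estimate, search_radius = 15) {
  if (background_estimate < 0) stop("background_estimate must be >= 0")
  region <- ball_region(image$grid, center, search_radius)
  if (!any(region)) stop("search radius contains no voxels")
  mx <- suv_max(image, region)
  if (mx$value <= background_estimate)
    stop("no object: local maximum does not exceed the background estimate")
  thr <- background_estimate + 0.5 * (mx$value - background_estimate)
  d <- dim(image$values)
  av <- as.vector(image$values >= thr)
  seed <- mx$index[1] + (mx$index[2] - 1) * d[1] + (mx$index[3] - 1) * d[1] * d[2]
  # 26-connected flood fill from the local-max voxel over voxels >= T;
  # neighbours computed in array coordinates so faces never wrap
  mask <- logical(prod(d))
  mask[seed] <- TRUE
  frontier <- matrix(mx$index, ncol = 3)
  while (nrow(frontier)) {
    nxt <- NULL
    for (j in seq_len(nrow(NEIGHBORS_26))) {
      ci <- sweep(frontier, 2, NEIGHBORS_26[j, ], "+")
      keep <- ci[, 1] >= 1 & ci[, 1] <= d[1] & ci[, 2] >= 1 & ci[, 2] <= d[2] &
        ci[, 3] >= 1 & ci[, 3] <= d[3]
      if (!any(keep)) next
      ci <- ci[keep, , drop = FALSE]
      lin <- ci[, 1] + (ci[, 2] - 1) * d[1] + (ci[, 3] - 1) * d[1] * d[2]
      new <- av[lin] & !mask[lin]
      if (any(new)) {
        mask[lin[new]] <- TRUE
        nxt <- rbind(nxt, ci[new, , drop = FALSE])
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else unique(nxt)
  }
  mask <- array(mask, dim = d)
  list(mask = mask, threshold = thr, local_max = mx$value,
       volume_mL = sum(mask) * voxel_volume_mm3(image$grid) / 1000,
       index = mx$index)
}

#' Logical ball region around a world point
#'
#' @param grid a [grid_spec()].
#' @param center world point, mm.
#' @param radius mm.
#' @export
ball_region <- function(grid, center, radius) {
  cx <- grid_axis_centers(grid, 1) - center[1]
  cy <- grid_axis_centers(grid, 2) - center[2]
  cz <- grid_axis_centers(grid, 3) - center[3]
  o <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  o <= radius^2
}

#' Mean uptake over a mask (SUVmean)
#'
#' @param image an [activity_image()].
#' @param mask logical array matching the image.
#' @export
suv_mean <- function(image, mask) {
  mask <- region_to_mask(image, mask)
  if (!any(mask)) stop("empty mask")
  mean(image$values[mask])
}

#' Recovery coefficient
#'
#' Ratio of an observed uptake value to the true activity concentration.
#'
#' @param observed measured concentration, kBq/mL.
#' @param true_concentration true concentration, kBq/mL (> 0).
#' @export
recovery_coefficient <- function(observed, true_concentration) {
  if (!is.finite(true_concentration) || true_concentration <= 0)
    stop("true_concentration must be > 0")
  observed / true_concentration
}

#' Background region mask for the IQ analysis
#'
#' Voxels inside the phantom's background compartment that keep a
#' clearance from every sphere and from the grid faces; the mean over
#' this region estimates `B` for the background-corrected isocontour.
#'
#' @param image an [activity_image()].
#' @param sc the (already transformed) truth [scene()].
#' @param clearance_mm minimum distance from each sphere surface, mm.
#' @param edge_margin_mm minimum distance from the grid faces, mm.
#' @export
background_region_mask <- function(image, sc, clearance_mm = 17.5,
                                   edge_margin_mm = 4) {
  grid <- image$grid
  mask <- array(TRUE, dim = grid$dim)
  centers <- sc$meta$sphere_centers
  diams <- sc$meta$sphere_diameters
  for (i in seq_len(nrow(centers)))
    mask <- mask & !ball_region(grid, centers[i, ], diams[i] / 2 + clearance_mm)
  ext <- grid_extent(grid)
  for (a in 1:3) {
    c_ax <- grid_axis_centers(grid, a)
    bad <- c_ax < ext[1, a] + edge_margin_mm | c_ax > ext[2, a] - edge_margin_mm
    if (any(bad)) {
      idx <- list(1:grid$dim[1], 1:grid$dim[2], 1:grid$dim[3])
      idx[[a]] <- which(bad)
      mask[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
    }
  }
  # restrict to the background compartment where the scene has one
  bg <- Filter(function(cp) identical(cp$name, "background"), sc$compartments)
  if (length(bg)) {
    inside <- shape_contains(bg[[1]]$shape, grid_voxel_centers(grid))
    mask <- mask & array(inside, dim = grid$dim)
  }
  if (!any(mask)) stop("background region is empty; enlarge the grid or reduce clearance")
  mask
}

#' Quantify all spheres of one IQ replicate
#'
#' For each sphere: the background-corrected 50% isocontour is seeded at
#' the sphere's true (transform-propagated) centre, then SUVmax, SUVpeak
#' and SUVmean are measured and converted to recovery coefficients using
#' the true concentrations. Sphere positions come from simulation
#' provenance, so no image registration is involved. A segmentation
#' failure yields a flagged row (`ok = FALSE`) rather than a dropped
#' sphere.
#'
#' @param image an [activity_image()] of the IQ (or single-sphere) scene.
#' @param sc the truth [scene()] in its original (untransformed) pose.
#' @param transform the [rigid_transform()] applied to this replicate;
#'   defaults to the one recorded in the image provenance.
#' @param kernel optional [make_peak_kernel()] on the image grid (built
#'   on demand when NULL).
#' @param background_estimate `B` in kBq/mL; when NULL it is the image
#'   mean over [background_region_mask()].
#' @param search_margin_mm margin added to each sphere radius for the
#'   max/peak search region, mm.
#' @param replicate,condition,recon_label,frame_duration bookkeeping
#'   fields copied into the output.
#' @return data.frame with one row per sphere: SUVs, RCs, segmented
#'   volume and identifiers.
#' @export
measure_iq_replicate <- function(image, sc, transform = NULL, kernel = NULL,
                                 background_estimate = NULL,
                                 search_margin_mm = 10,
                                 replicate = NA_integer_,
                                 condition = NA_character_,
                                 recon_label = NA_character_,
                                 frame_duration = NA_real_) {
  if (is.null(transform))
    transform <- image$provenance$transform %||% rigid_transform()
  truth <- if (is_identity_transform(transform)) sc else apply_transform(sc, transform)
  centers <- truth$meta$sphere_centers
  diams <- truth$meta$sphere_diameters
  s_true <- truth$meta$sphere_concentration
  if (is.null(kernel)) kernel <- make_peak_kernel(image$grid)
  if (is.null(background_estimate)) {
    bg_mask <- background_region_mask(image, truth)
    background_estimate <- mean(image$values[bg_mask])
  }
  rows <- vector("list", length(diams))
  for (i in seq_along(diams)) {
    ctr <- centers[i, ]
    rad <- diams[i] / 2
    row <- data.frame(sphere_mm = diams[i], replicate = replicate,
                      condition = condition, recon = recon_label,
                      frame_duration = frame_duration,
                      suv_max = NA_real_, suv_peak = NA_real_, suv_mean = NA_real_,
                      rc_max = NA_real_, rc_peak = NA_real_, rc_mean = NA_real_,
                      volume_mL = NA_real_, background = background_estimate,
                      ok = FALSE)
    res <- try({
      region <- ball_region(image$grid, ctr, rad + search_margin_mm)
      seg <- segment_a50(image, ctr, background_estimate,
                         search_radius = rad + search_margin_mm / 2)
      mx <- suv_max(image, region)
      pk <- suv_peak(image, kernel, region)
      mn <- suv_mean(image, seg$mask)
      row$suv_max <- mx$value; row$suv_peak <- pk$value; row$suv_mean <- mn
      row$rc_max <- recovery_coefficient(mx$value, s_true)
      row$rc_peak <- recovery_coefficient(pk$value, s_true)
      row$rc_mean <- recovery_coefficient(mn, s_true)
      row$volume_mL <- seg$volume_mL
      row$ok <- TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      attr(rows, "errors") <- c(attr(rows, "errors"), conditionMessage(attr(res, "condition")))
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Regional means over a realigned brain VOI template
#'
#' Maps each template VOI rigidly into image space (template voxel
#' centres are transformed and the image is sampled by nearest
#' neighbour) and reports per-VOI means and recovery coefficients
#' relative to the fill-solution concentration. The realignment is
#' usually the ground-truth repositioning transform from provenance,
#' optionally perturbed to emulate registration error.
#'
#' @param image an [activity_image()] of the brain scene.
#' @param template a brain template from [build_brain_scene()].
#' @param realignment a [rigid_transform()] mapping template space to
#'   image space; default identity.
#' @param replicate,condition,recon_label,frame_duration bookkeeping
#'   fields copied into the output.
#' @return data.frame with one row per VOI: mean concentration and
#'   `rc_mean = mean / solution_concentration`.
#' @export
region_means <- function(image, template, realignment = rigid_transform(),
                         replicate = NA_integer_, condition = NA_character_,
                         recon_label = NA_character_, frame_duration = NA_real_) {
  grid <- image$grid
  d <- grid$dim
  rows <- vector("list", length(template$vois))
  for (i in seq_along(template$vois)) {
    voi <- template$vois[[i]]
    pts <- transform_points(realignment, voi$centers_mm)
    idx <- sweep(pts, 2, grid$origin)
    idx <- 1L + floor(sweep(idx, 2, grid$voxel_size, "/"))
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (!any(ok))
      stop(sprintf("VOI '%s' is empty after realignment", voi$name))
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * d[1] + (idx[ok, 3] - 1) * d[1] * d[2]
    m <- mean(image$values[lin])
    rows[[i]] <- data.frame(region = voi$name, tissue = voi$tissue,
                            n_voxels = sum(ok), mean = m,
                            rc_mean = m / template$solution_concentration,
                            replicate = replicate, condition = condition,
                            recon = recon_label, frame_duration = frame_duration)
  }
  do.call(rbind, rows)
}
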