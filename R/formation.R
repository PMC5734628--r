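FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # fwhm * this = sigma

# separable 1-D Gaussian taps in voxel units, truncated at 4 sigma
gauss_taps <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# 1-D convolution matrix with replicate (nearest) padding; replicate
# padding leaves uniform surroundings exactly uniform, so grids cropped
# inside a uniform background stay unbiased at their edges
conv_matrix <- function(n, taps) {
  r <- (length(taps) - 1L) %/% 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(taps)) {
    j <- pmin(pmax(i + (k - 1L - r), 1L), n)
    K[cbind(i, j)] <- K[cbind(i, j)] + taps[k]
  }
  K
}

# convolution along one axis: dense banded-matrix multiply (BLAS) for
# short axes, shift-add tap loop for long ones where O(n^2) would lose
conv_axis <- function(arr, taps, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n <= 160L) {
    K <- conv_matrix(n, taps)
    out <- switch(axis,
      array(K %*% matrix(arr, n, d[2] * d[3]), dim = d),
      aperm(array(K %*% matrix(aperm(arr, c(2L, 1L, 3L)), n, d[1] * d[3]),
                  dim = d[c(2L, 1L, 3L)]), c(2L, 1L, 3L)),
      array(matrix(arr, d[1] * d[2], n) %*% t(K), dim = d))
    return(out)
  }
  r <- (length(taps) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (k in seq_along(taps)) {
    idx <- pmin(pmax(seq_len(n) + (k - 1L - r), 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + taps[k] * shifted
  }
  out
}

gaussian_blur_array <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    if (sigma_vox[axis] < 0.05) next
    arr <- conv_axis(arr, gauss_taps(sigma_vox[axis]), axis)
  }
  arr
}

#' Gaussian resolution blur
#'
#' Convolves an image with an isotropic Gaussian of the given full width
#' at half maximum (sigma = fwhm / 2.3548), emulating the finite spatial
#' resolution of a reconstructed PET image. The kernel is separable,
#' truncated at 4 sigma and renormalized; boundary handling is replicate
#' padding, which preserves uniform regions exactly. `fwhm = 0` is the
#' identity.
#'
#' @param image an [activity_image()].
#' @param fwhm full width at half maximum in mm (>= 0).
#' @export
blur_image <- function(image, fwhm) {
  if (!is.finite(fwhm) || fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(note_provenance(image, "blur", list(fwhm = 0)))
  sigma_vox <- fwhm * FWHM_TO_SIGMA / image$grid$voxel_size
  vals <- gaussian_blur_array(image$values, sigma_vox)
  note_provenance(activity_image(vals, image$grid, image$provenance),
                  "blur", list(fwhm = fwhm))
}

#' Post-reconstruction resolution modelling (iterative deconvolution)
#'
#' Richardson-Lucy iterative deconvolution with an isotropic Gaussian
#' kernel, emulating vendor resolution modelling implemented as a
#' post-reconstruction deconvolution. Zero iterations is the identity;
#' the output is non-negative and renormalized so that total activity
#' equals that of the (non-negative part of the) input. Edge
#' sharpening and Gibbs-type overshoot at sharp boundaries are expected
#' behaviour of this operator.
#'
#' @param image an [activity_image()].
#' @param kernel_fwhm deconvolution kernel FWHM, mm (> 0 when
#'   `iterations` > 0).
#' @param iterations number of Richardson-Lucy iterations (>= 0).
#' @export
psf_enhance <- function(image, kernel_fwhm, iterations) {
  iterations <- as.integer(iterations)
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0L) return(image)
  if (!is.finite(kernel_fwhm) || kernel_fwhm <= 0)
    stop("kernel_fwhm must be > 0 when iterations > 0")
  sigma_vox <- kernel_fwhm * FWHM_TO_SIGMA / image$grid$voxel_size
  obs <- pmax(image$values, 0)
  eps <- 1e-12 * max(obs, 1e-30)
  est <- obs
  for (i in seq_len(iterations)) {
    conv <- gaussian_blur_array(est, sigma_vox)
    ratio <- obs / pmax(conv, eps)
    est <- est * gaussian_blur_array(ratio, sigma_vox)  # Gaussian kernel is symmetric: adjoint = forward
  }
  tot_in <- sum(obs)
  tot_out <- sum(est)
  if (tot_out > 0) est <- est * (tot_in / tot_out)
  note_provenance(activity_image(est, image$grid, image$provenance),
                  "psf", list(kernel_fwhm = kernel_fwhm, iterations = iterations))
}

#' Decay-compensated equal-count frame schedule
#'
#' Builds contiguous frames starting at t = 0 whose durations increase so
#' that each frame collects exactly the same expected number of true
#' counts from a source decaying with the given half-life:
#' the integral of `exp(-lambda t)` over every frame equals that over the
#' first frame, `lambda = ln 2 / half_life`. With `half_life = Inf` all
#' durations equal the first.
#'
#' @param first_duration duration of frame 1 in minutes (> 0).
#' @param n_frames number of frames (>= 1).
#' @param half_life radionuclide half-life in minutes; default 109.77
#'   (fluorine-18).
#' @return An object of class `frame_schedule` with `start`, `duration`
#'   (minutes) and `half_life`.
#' @export
equal_counts_schedule <- function(first_duration, n_frames, half_life = 109.77) {
  if (!is.finite(first_duration) || first_duration <= 0)
    stop("first_duration must be > 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (is.na(half_life) || half_life <= 0) stop("half_life must be > 0 (may be Inf)")
  if (is.infinite(half_life)) {
    start <- (seq_len(n_frames) - 1) * first_duration
    duration <- rep(first_duration, n_frames)
  } else {
    lam <- log(2) / half_life
    C <- 1 - exp(-lam * first_duration)   # per-frame decay integral * lambda
    if (n_frames * C >= 1)
      stop("schedule infeasible: activity fully decayed before the last frame")
    ends <- -log(1 - seq_len(n_frames) * C) / lam
    start <- c(0, ends[-n_frames])
    duration <- ends - start
  }
  structure(list(start = start, duration = duration, half_life = half_life),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g .. %.4g min, half-life %.4g min\n",
              length(x$duration), x$duration[1], x$duration[length(x$duration)],
              x$half_life))
  invisible(x)
}

#' Expected relative counts per frame
#'
#' Integral of the decay curve over each frame (relative to unit initial
#' activity), used to verify equal count statistics across frames.
#'
#' @param schedule a [frame_schedule()].
#' @export
frame_expected_counts <- function(schedule) {
  if (is.infinite(schedule$half_life)) return(schedule$duration)
  lam <- log(2) / schedule$half_life
  (exp(-lam * schedule$start) - exp(-lam * (schedule$start + schedule$duration))) / lam
}

frame_decay_factor <- function(schedule, frame) {
  if (is.infinite(schedule$half_life)) return(1)
  lam <- log(2) / schedule$half_life
  mid <- schedule$start[frame] + schedule$duration[frame] / 2
  exp(-lam * mid)
}

#' Count-statistics noise model
#'
#' A voxel-level Poisson surrogate for reconstruction noise: expected
#' counts in a voxel are `concentration x voxel_volume_mL x duration_min x
#' counts_per_mL_per_min x decay factor at the frame midpoint`; sampled
#' counts are rescaled back to concentration units. Relative noise
#' therefore falls as one over the square root of the collected counts,
#' reproducing the dependence of image variability on frame duration. An
#' optional Gaussian post-filter correlates the noise.
#'
#' @param counts_per_mL_per_min scale linking kBq/mL times minutes to
#'   expected voxel counts (> 0). The default 600 corresponds to roughly
#'   1% counting sensitivity for a kBq source.
#' @param post_filter_fwhm mm; 0 disables the post-filter.
#' @param seed integer RNG seed used by [add_noise()].
#' @export
noise_model <- function(counts_per_mL_per_min = 600, post_filter_fwhm = 0,
                        seed = 1L) {
  if (!is.finite(counts_per_mL_per_min) || counts_per_mL_per_min <= 0)
    stop("counts_per_mL_per_min must be > 0")
  if (post_filter_fwhm < 0) stop("post_filter_fwhm must be >= 0")
  structure(list(counts_per_mL_per_min = counts_per_mL_per_min,
                 post_filter_fwhm = post_filter_fwhm,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add count-statistics noise to an image
#'
#' @param image an [activity_image()] in kBq/mL.
#' @param noise a [noise_model()].
#' @param schedule a [frame_schedule()]; supplies the frame duration and
#'   midpoint decay factor.
#' @param frame frame index into the schedule.
#' @param quantile_coupled if TRUE, counts are drawn by quantile
#'   inversion (`qpois` of one uniform per voxel) instead of direct
#'   Poisson sampling. Marginal distributions are identical; the point is
#'   common random numbers: calls with the same seed but different count
#'   scales yield comonotone noise, the standard coupling for paired
#'   comparisons across noise levels.
#' @return A noisy [activity_image()] in concentration units;
#'   reproducible for a fixed `noise$seed`.
#' @export
add_noise <- function(image, noise, schedule, frame = 1L,
                      quantile_coupled = FALSE) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > length(schedule$duration))
    stop("frame index outside schedule")
  voxel_mL <- voxel_volume_mm3(image$grid) / 1000
  scale <- voxel_mL * schedule$duration[frame] * noise$counts_per_mL_per_min *
    frame_decay_factor(schedule, frame)
  lam <- pmax(image$values, 0) * scale
  vals <- with_seed(noise$seed, {
    counts <- if (quantile_coupled)
      stats::qpois(stats::runif(length(lam)), lam)
    else stats::rpois(length(lam), lam)
    array(counts / scale, dim = dim(lam))
  })
  out <- activity_image(vals, image$grid, image$provenance)
  if (noise$post_filter_fwhm > 0)
    out <- blur_image(out, noise$post_filter_fwhm)
  note_provenance(out, "noise",
                  list(seed = noise$seed, frame = frame,
                       duration = schedule$duration[frame],
                       counts_per_mL_per_min = noise$counts_per_mL_per_min))
}

#' Reconstruction profile
#'
#' Bundles an output grid, an effective resolution and optional
#' resolution-modelling settings into one named "reconstruction". Two
#' emulation styles are provided by [iq_recon_profiles()]: a baseline
#' profile (blur only) and a resolution-modelled profile (blur followed
#' by Richardson-Lucy deconvolution, or a sharper direct blur for
#' in-reconstruction modelling).
#'
#' @param grid output [grid_spec()].
#' @param fwhm effective resolution FWHM in mm (> 0).
#' @param psf_iterations Richardson-Lucy iterations (0 = no resolution
#'   modelling).
#' @param psf_kernel_fwhm deconvolution kernel FWHM, mm.
#' @param fine_factor integer refinement factor of the internal
#'   simulation grid; default places the fine grid at roughly 1 mm
#'   spacing so that effective resolution is independent of the output
#'   voxel size.
#' @param label profile name.
#' @export
recon_profile <- function(grid, fwhm = 7, psf_iterations = 0L,
                          psf_kernel_fwhm = fwhm,
                          fine_factor = NULL, label = "recon") {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  if (psf_iterations < 0) stop("psf_iterations must be >= 0")
  if (is.null(fine_factor))
    fine_factor <- pmax(2L, as.integer(ceiling(grid$voxel_size / 1.25)))
  fine_factor <- as.integer(rep_len(fine_factor, 3L))
  structure(list(grid = grid, fwhm = fwhm,
                 psf_iterations = as.integer(psf_iterations),
                 psf_kernel_fwhm = psf_kernel_fwhm,
                 fine_factor = fine_factor, label = label),
            class = "recon_profile")
}

#' @export
print.recon_profile <- function(x, ...) {
  cat(sprintf("<recon_profile> %s: %.4g x %.4g x %.4g mm voxels, FWHM %.3g mm%s\n",
              x$label, x$grid$voxel_size[1], x$grid$voxel_size[2], x$grid$voxel_size[3],
              x$fwhm,
              if (x$psf_iterations > 0)
                sprintf(", RL deconv %d it (kernel %.3g mm)", x$psf_iterations, x$psf_kernel_fwhm)
              else ""))
  invisible(x)
}

#' Standard reconstruction profiles for the IQ phantom study
#'
#' The four voxel-size settings of the study design: body-mode
#' 4 x 4 x 4 mm and 2 x 2 x 2 mm grids (one vendor style) and
#' 3.1819 x 3.1819 x 2 mm and 2.0364 x 2.0364 x 2 mm grids (the other),
#' each with and without resolution modelling. Baseline profiles use a
#' 7 mm effective resolution; "+PSF" profiles add 10 Richardson-Lucy
#' iterations with a 7 mm kernel (post-reconstruction style) or use a
#' direct 5 mm resolution (in-reconstruction style). Resolutions are
#' configurable emulation parameters, not vendor measurements.
#'
#' @param extent_mm world extents (x, y, z) the grids must cover,
#'   centred on the origin; default covers the IQ phantom.
#' @param fwhm baseline effective resolution, mm.
#' @param psf_fwhm in-reconstruction modelled resolution, mm.
#' @param psf_iterations Richardson-Lucy iterations for
#'   post-reconstruction modelling.
#' @return Named list of [recon_profile()]s.
#' @export
iq_recon_profiles <- function(extent_mm = c(320, 240, 200), fwhm = 7,
                              psf_fwhm = 5, psf_iterations = 10L) {
  centred_grid <- function(vs) {
    d <- as.integer(ceiling(extent_mm / vs))
    grid_spec(vs, d, -d * vs / 2)
  }
  vox <- list("4mm" = c(4, 4, 4), "2mm" = c(2, 2, 2),
              "3.18mm" = c(3.1819, 3.1819, 2), "2.04mm" = c(2.0364, 2.0364, 2))
  out <- list()
  for (nm in names(vox)) {
    g <- centred_grid(vox[[nm]])
    out[[paste0("TOF-", nm)]] <-
      recon_profile(g, fwhm = fwhm, psf_iterations = 0L,
                    label = paste0("TOF-", nm))
    style_post <- nm %in% c("4mm", "2mm")
    out[[paste0("TOF+PSF-", nm)]] <- if (style_post)
      recon_profile(g, fwhm = fwhm, psf_iterations = psf_iterations,
                    psf_kernel_fwhm = fwhm, label = paste0("TOF+PSF-", nm))
    else
      recon_profile(g, fwhm = psf_fwhm, psf_iterations = 0L,
                    label = paste0("TOF+PSF-", nm))
  }
  out
}

#' Simulate one reconstructed replicate
#'
#' Runs the acquisition chain for a single replicate: rigidly transform
#' the scene (repositioning), voxelize on the profile's fine internal
#' grid, blur to the effective resolution, optionally apply
#' Richardson-Lucy resolution modelling, block-average down to the output
#' grid, and add count-statistics noise for the requested frame. Every
#' step is recorded in the image provenance.
#'
#' @param sc a [scene()].
#' @param profile a [recon_profile()].
#' @param schedule a [frame_schedule()]; required when `noise` is given.
#' @param frame frame index.
#' @param transform a [rigid_transform()]; default identity.
#' @param noise a [noise_model()] or NULL for a noiseless replicate.
#' @param supersampling subvoxel samples per axis for voxelization.
#' @param check_coverage passed to [voxelize_scene()]; set FALSE for
#'   windowed sub-grids that deliberately crop the scene.
#' @return An [activity_image()] on `profile$grid`.
#' @export
simulate_replicate <- function(sc, profile, schedule = NULL, frame = 1L,
                               transform = rigid_transform(), noise = NULL,
                               supersampling = 4L, check_coverage = TRUE) {
  moved <- if (is_identity_transform(transform)) sc else apply_transform(sc, transform)
  fine <- refine_grid(profile$grid, profile$fine_factor)
  img <- voxelize_scene(moved, fine, supersampling = supersampling,
                        check_coverage = check_coverage)
  img <- blur_image(img, profile$fwhm)
  if (profile$psf_iterations > 0L)
    img <- psf_enhance(img, profile$psf_kernel_fwhm, profile$psf_iterations)
  img <- downsample_image(img, profile$fine_factor)
  img <- note_provenance(img, "transform", transform)
  img <- note_provenance(img, "profile", list(label = profile$label,
                                              fwhm = profile$fwhm,
                                              psf_iterations = profile$psf_iterations))
  if (!is.null(noise)) {
    if (is.null(schedule)) stop("a frame schedule is required to add noise")
    img <- add_noise(img, noise, schedule, frame)
  }
  img
}

#' Write a simulated replicate with its provenance sidecar
#'
#' Writes the image as NIfTI-1 plus a JSON sidecar holding the applied
#' transform, blur, resolution-modelling and noise records.
#'
#' @param image an [activity_image()] from [simulate_replicate()].
#' @param path output path without extension.
#' @export
write_replicate <- function(image, path) {
  write_activity_image(image, paste0(path, ".nii.gz"))
  prov <- image$provenance
  if (!is.null(prov$transform))
    prov$transform <- list(rotation_deg = prov$transform$rotation_deg,
                           translation_mm = prov$transform$translation_mm,
                           matrix = as.vector(prov$transform$matrix))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}
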