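# Independent oracles and small fixture builders shared across tests.

# Closed-form centre value of a uniform sphere (radius R, concentration S)
# in background B after isotropic Gaussian blur of the given FWHM.
blurred_sphere_center <- function(R, fwhm, S, B) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  x <- R / sigma
  B + (S - B) * (2 * stats::pnorm(x) - 1 - sqrt(2 / pi) * x * exp(-x^2 / 2))
}

# Single sphere at the origin with its centre on a voxel centre of an
# odd-dimension grid (so the discrete maximum can be compared with the
# analytic centre value).
aligned_sphere_image <- function(diameter, S, B, voxel_mm, fwhm = 0,
                                 margin_mm = 22, supersampling = 4) {
  sc <- build_sphere_scene(diameter, S, B,
                           half_extent = diameter / 2 + margin_mm + 10)
  n <- 2 * ceiling((diameter / 2 + margin_mm) / voxel_mm) + 1
  g <- grid_spec(voxel_mm, c(n, n, n), origin = rep(-n * voxel_mm / 2, 3))
  img <- voxelize_scene(sc, g, supersampling, check_coverage = FALSE)
  if (fwhm > 0) img <- blur_image(img, fwhm)
  list(image = img, scene = sc, grid = g)
}

# Windowed single-sphere replicate used by precision studies in tests.
windowed_profile <- function(profile, center, half_extent) {
  wg <- crop_grid(profile$grid, center, half_extent)
  recon_profile(wg, fwhm = profile$fwhm,
                psf_iterations = profile$psf_iterations,
                psf_kernel_fwhm = profile$psf_kernel_fwhm,
                fine_factor = profile$fine_factor, label = profile$label)
}
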