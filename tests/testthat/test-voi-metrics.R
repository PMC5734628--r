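test_that("peak kernels are symmetric, bounded and fail on degenerate grids", {
  k <- make_peak_kernel(grid_spec(2, c(20, 20, 20)))
  expect_true(all(k$weights >= 0 & k$weights <= 1))
  expect_equal(k$radius_mm, (3 * 1000 / (4 * pi))^(1 / 3), tolerance = 1e-9)
  # axis-permutation symmetry on isotropic voxels
  key <- function(o) paste(o[, 1], o[, 2], o[, 3])
  w <- setNames(k$weights, key(k$offsets))
  expect_equal(unname(w[key(k$offsets[, c(2, 3, 1)])]), k$weights, tolerance = 1e-9)
  expect_error(make_peak_kernel(grid_spec(c(14, 2, 2), c(8, 8, 8))), "degenerate")
})

test_that("suv_max takes the regional maximum with deterministic ties", {
  g <- grid_spec(2, c(6, 6, 6))
  vals <- array(3, c(6, 6, 6))
  img <- activity_image(vals, g)
  all_region <- array(TRUE, c(6, 6, 6))
  expect_equal(suv_max(img, all_region)$value, 3)
  # tie broken at the lowest linear index
  vals[c(10, 40)] <- 9
  img <- activity_image(vals, g)
  res <- suv_max(img, all_region)
  expect_equal(res$value, 9)
  expect_equal(res$index, arrayInd(10, c(6, 6, 6))[1, ], ignore_attr = TRUE)
  expect_error(suv_max(img, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("suv_peak is the best kernel average and never exceeds suv_max", {
  g <- grid_spec(2, c(14, 14, 14))
  k <- make_peak_kernel(g)
  const <- activity_image(array(4.2, c(14, 14, 14)), g)
  all_region <- array(TRUE, c(14, 14, 14))
  expect_equal(suv_peak(const, k, all_region)$value, 4.2, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    img <- activity_image(array(runif(14^3), c(14, 14, 14)), g)
    pk <- suv_peak(img, k, all_region)$value
    mx <- suv_max(img, all_region)$value
    expect_lte(pk, mx + 1e-12)
  }
  # a sphere smaller than the 1 mL VOI dilutes the peak with background
  fx <- aligned_sphere_image(10, 10, 1, voxel_mm = 1, fwhm = 7)
  k1 <- make_peak_kernel(fx$grid)
  pk <- suv_peak(fx$image, k1, ball_region(fx$grid, c(0, 0, 0), 10))$value
  expect_lt(pk, blurred_sphere_center(5, 7, 10, 1))
  expect_gt(pk, 1)
})

test_that("A50 segmentation applies the background-corrected threshold", {
  g <- grid_spec(2, c(15, 15, 15), origin = rep(-15, 3))
  vals <- array(1, c(15, 15, 15))
  ctr <- c(8, 8, 8)
  vals[6:10, 6:10, 6:10] <- 6
  vals[ctr[1], ctr[2], ctr[3]] <- 10
  img <- activity_image(vals, g)
  seg <- segment_a50(img, c(0, 0, 0), background_estimate = 1, search_radius = 8)
  expect_equal(seg$threshold, 5.5)   # B + 0.5 (max - B) with B = 1, max = 10
  expect_equal(sum(seg$mask), 125)   # the 5^3 block sits above threshold
  expect_error(segment_a50(activity_image(array(1, c(15, 15, 15)), g),
                           c(0, 0, 0), 1, search_radius = 8), "no object")
})

test_that("A50 volumes match the analytic sphere volume", {
  # unblurred 37 mm sphere: within a voxel shell of 26.52 mL
  fx <- aligned_sphere_image(37, 20, 2, voxel_mm = 2, margin_mm = 14)
  seg <- segment_a50(fx$image, c(0, 0, 0), 2, search_radius = 20)
  expect_equal(seg$volume_mL, 4 / 3 * pi * 18.5^3 / 1000, tolerance = 0.05)
  # blurred at 7 mm: the 50% isocontour still approximates an object
  # much larger than the resolution
  fxb <- aligned_sphere_image(37, 20, 2, voxel_mm = 2, fwhm = 7, margin_mm = 18)
  segb <- segment_a50(fxb$image, c(0, 0, 0), 2, search_radius = 20)
  expect_equal(segb$volume_mL, 26.52, tolerance = 0.15)
})

test_that("suv_mean is the unweighted mask mean and combines linearly", {
  g <- grid_spec(2, c(8, 8, 8))
  img <- activity_image(array(seq_len(512) / 10, c(8, 8, 8)), g)
  m1 <- array(FALSE, c(8, 8, 8)); m1[1:50] <- TRUE
  m2 <- array(FALSE, c(8, 8, 8)); m2[101:130] <- TRUE
  both <- m1 | m2
  expect_equal(suv_mean(img, both),
               (50 * suv_mean(img, m1) + 30 * suv_mean(img, m2)) / 80)
  cimg <- activity_image(array(2.5, c(8, 8, 8)), g)
  expect_equal(suv_mean(cimg, m1), 2.5)
  expect_error(suv_mean(img, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("recovery coefficients are observed over true", {
  expect_equal(recovery_coefficient(10, 10), 1)
  expect_equal(recovery_coefficient(6.23, 10), 0.623)
  expect_equal(recovery_coefficient(0, 10), 0)
  expect_error(recovery_coefficient(5, 0), "true_concentration")
})

test_that("measure_iq_replicate quantifies all six spheres from provenance", {
  sc <- build_iq_scene(20, 2)
  g <- grid_spec(4, c(80, 62, 26), origin = c(-160, -124, -52))
  img <- voxelize_scene(sc, g, supersampling = 2, check_coverage = FALSE)
  m <- measure_iq_replicate(img, sc)
  expect_equal(nrow(m), 6)
  expect_true(all(m$ok))
  expect_true(all(m$rc_max >= m$rc_peak))
  # unblurred: every sphere >= 13 mm has a fully interior voxel
  expect_equal(m$rc_max[m$sphere_mm >= 13], rep(1, 5), tolerance = 0.01)
  expect_true(all(m$volume_mL > 0))
})

test_that("metrics run identically on NIfTI input", {
  fx <- aligned_sphere_image(17, 20, 2, voxel_mm = 2, fwhm = 7, margin_mm = 14)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_activity_image(fx$image, f)
  img2 <- read_activity_image(f)
  reg <- ball_region(img2$grid, c(0, 0, 0), 14)
  expect_equal(suv_max(img2, reg)$value,
               suv_max(fx$image, ball_region(fx$grid, c(0, 0, 0), 14))$value,
               tolerance = 1e-6)
  seg <- segment_a50(img2, c(0, 0, 0), 2, search_radius = 12)
  expect_gt(sum(seg$mask), 0)
})

test_that("brain VOI means show spill-out from gray and spill-in to white", {
  bb <- build_brain_scene(10, 4)
  img <- blur_image(voxelize_scene(bb$scene, bb$template$grid, supersampling = 2), 7)
  rm1 <- region_means(img, bb$template)
  gray <- rm1$tissue == "gray"
  expect_true(all(rm1$rc_mean[gray] < 1))
  # white regions gain counts from the hotter gray matter
  expect_true(all(rm1$mean[!gray] > 2.5))
})

test_that("realigning the template with the true transform recovers regional means", {
  bb <- build_brain_scene(10, 4)
  tgrid <- bb$template$grid
  big <- grid_spec(tgrid$voxel_size, tgrid$dim + 20L,
                   tgrid$origin - 10 * tgrid$voxel_size)
  stationary <- blur_image(voxelize_scene(bb$scene, big, 1, check_coverage = FALSE), 7)
  tr <- rigid_transform(rotation_deg = c(2, -1, 3), translation_mm = c(10, -8, 6))
  moved <- blur_image(voxelize_scene(apply_transform(bb$scene, tr), big, 1,
                                     check_coverage = FALSE), 7)
  r_stat <- region_means(stationary, bb$template)
  r_true <- region_means(moved, bb$template, realignment = tr)
  r_none <- region_means(moved, bb$template)
  err_true <- abs(r_true$mean - r_stat$mean)
  err_none <- abs(r_none$mean - r_stat$mean)
  expect_true(all(err_true <= err_none))
  expect_lt(max(err_true), 0.2)
})
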