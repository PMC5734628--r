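test_that("IQ scene reproduces the standard phantom geometry", {
  sc <- build_iq_scene(20, 2)
  diams <- sapply(sc$compartments[-1], function(cp) 2 * cp$shape$radius)
  expect_equal(sort(diams), c(10, 13, 17, 22, 28, 37))
  # coplanar centres on the 57.2 mm ring
  ctrs <- sc$meta$sphere_centers
  expect_equal(unname(sqrt(rowSums(ctrs[, 1:2]^2))), rep(57.2, 6))
  expect_equal(unname(ctrs[, 3]), rep(0, 6))
  # background vessel volume is the 9400 mL of the physical phantom
  bg <- sc$compartments[[1]]$shape
  expect_equal(shape_volume_mm3(bg) / 1000, 9400, tolerance = 1e-6)
  # EARL-style fills give the ~10:1 contrast
  sc2 <- build_iq_scene(17.78, 1.75)
  expect_equal(17.78 / 1.75, 10.16, tolerance = 1e-3)
  expect_equal(sc2$compartments[[2]]$concentration, 17.78)
  expect_error(build_iq_scene(-1, 2), "sphere_concentration")
  expect_error(build_iq_scene(20, 0), "background_concentration")
  expect_error(build_sphere_scene(10, 20, -1), "background_concentration")
})

test_that("equal fill concentrations voxelize to a constant inside the phantom", {
  sc <- build_iq_scene(2, 2)
  # window fully interior to the vessel, away from its wall
  g <- grid_spec(4, c(12, 12, 12), origin = c(-24, -24, -24))
  img <- voxelize_scene(sc, g, supersampling = 2, check_coverage = FALSE)
  expect_true(all(abs(img$values - 2) < 1e-12))
})

test_that("voxelization conserves sphere volume with fractional coverage", {
  # 10 mm sphere on a 1 mm grid: excess over background recovers the
  # analytic volume 523.6 mm^3 within 2%
  fx <- aligned_sphere_image(10, 10, 0, voxel_mm = 1, margin_mm = 6)
  vol <- sum(fx$image$values / 10) * voxel_volume_mm3(fx$grid)
  expect_equal(vol, 4 / 3 * pi * 5^3, tolerance = 0.02)
  # conservation across diameters, grids and supersampling levels, with
  # the 1/supersampling relative tolerance the method guarantees
  for (d in c(13, 22)) for (vox in c(2, 4)) for (ss in c(2, 4)) {
    fx <- aligned_sphere_image(d, 10, 0, voxel_mm = vox, margin_mm = 8,
                               supersampling = ss)
    vol <- sum(fx$image$values / 10) * voxel_volume_mm3(fx$grid)
    true_vol <- 4 / 3 * pi * (d / 2)^3
    expect_lt(abs(vol - true_vol) / true_vol, 1 / ss)
  }
})

test_that("supersampling refinement converges", {
  sc <- build_sphere_scene(13, 10, 1, half_extent = 20)
  g <- grid_spec(2, c(15, 15, 15), origin = rep(-15, 3) + 0.4)
  v <- lapply(c(1, 2, 4), function(s)
    voxelize_scene(sc, g, s, check_coverage = FALSE)$values)
  d12 <- max(abs(v[[1]] - v[[2]]))
  d24 <- max(abs(v[[2]] - v[[3]]))
  expect_lt(d24, d12)
})

test_that("a large sphere on a coarse grid contains fully interior voxels", {
  fx <- aligned_sphere_image(37, 20, 2, voxel_mm = 4, margin_mm = 10)
  expect_identical(max(fx$image$values), 20)
})

test_that("scene validation rejects bad inputs", {
  expect_error(sphere_shape(c(0, 0, 0), -5), "diameter")
  expect_error(scene(list(list(shape = sphere_shape(c(0, 0, 0), 10),
                               concentration = -1))), "concentrations")
  expect_error(grid_spec(c(0, 1, 1), c(4, 4, 4)), "voxel_size")
  sc <- build_sphere_scene(10, 5, 1, half_extent = 30)
  small <- grid_spec(2, c(4, 4, 4), origin = c(0, 0, 0))
  expect_error(voxelize_scene(sc, small), "cover")
})

test_that("scenes roundtrip through JSON and images through NIfTI", {
  sc <- build_iq_scene(20, 2)
  f <- withr::local_tempfile(fileext = ".json")
  scene_to_json(sc, f)
  sc2 <- scene_from_json(f)
  expect_equal(length(sc2$compartments), 7)
  expect_equal(sc2$meta$sphere_centers, sc$meta$sphere_centers,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sc2$compartments[[2]]$shape$radius, 5)
  p <- iq_sphere_centers()[3, , drop = FALSE]
  expect_equal(scene_concentration_at(sc2, p), 20)

  g <- grid_spec(c(2, 2, 3), c(7, 6, 5), origin = c(-7, -6, -7.5))
  img <- activity_image(array(runif(210), c(7, 6, 5)), g)
  nf <- withr::local_tempfile(fileext = ".nii.gz")
  write_activity_image(img, nf)
  img2 <- read_activity_image(nf)
  expect_equal(img2$values, img$values, tolerance = 1e-6)
  expect_equal(img2$grid$voxel_size, g$voxel_size, tolerance = 1e-5)
  expect_equal(img2$grid$origin, g$origin, tolerance = 1e-4)
})

test_that("brain scene has the designed contrast and a consistent VOI template", {
  bb <- build_brain_scene(10, 4)
  white <- Filter(function(cp) identical(cp$name, "white"), bb$scene$compartments)
  expect_equal(white[[1]]$concentration, 2.5)
  expect_error(build_brain_scene(10, 1), "gray_white_ratio")
  expect_error(build_brain_scene(0, 4), "solution_concentration")

  tpl <- bb$template
  expect_length(tpl$vois, 20)
  tissues <- sapply(tpl$vois, `[[`, "tissue")
  expect_equal(unname(table(tissues)[c("gray", "white")]), c(10L, 10L),
               ignore_attr = TRUE)
  # disjoint within each tissue class, and every VOI inside its label set
  for (tis in c("gray", "white")) {
    idx <- unlist(lapply(tpl$vois[tissues == tis], `[[`, "index"))
    expect_equal(anyDuplicated(idx), 0)
    lab <- if (tis == "gray") 1L else 2L
    expect_true(all(tpl$labels[idx] == lab))
  }
  # sizes span small deep structures to large regions
  sizes <- sapply(tpl$vois, function(v) length(v$index))
  expect_gt(max(sizes) / min(sizes), 10)
})

test_that("noiseless unblurred brain VOI means recover the fill concentrations", {
  bb <- build_brain_scene(10, 4)
  img <- voxelize_scene(bb$scene, bb$template$grid, supersampling = 1)
  rm0 <- region_means(img, bb$template)
  expect_equal(rm0$mean[rm0$tissue == "gray"], rep(10, 10))
  expect_equal(rm0$mean[rm0$tissue == "white"], rep(2.5, 10))
  expect_equal(rm0$rc_mean[rm0$tissue == "gray"], rep(1, 10))
})
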