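test_that("repositioning draws respect their bounds and are centred", {
  expect_true(is_identity_transform(sample_transform(0, 0, seed = 1)))
  for (s in 1:300) {
    tr <- sample_transform(5, 20, seed = s)
    expect_true(all(abs(tr$rotation_deg) <= 5))
    expect_lte(sqrt(sum(tr$translation_mm^2)), 20)
  }
  # Monte-Carlo symmetry: mean translation ~ 0 within 3 standard errors
  n <- 2000
  tr <- t(sapply(seq_len(n), function(s)
    sample_transform(5, 20, seed = 10000 + s)$translation_mm))
  se <- sqrt(20^2 / 5 / n)  # per-axis variance of uniform-ball translation is R^2/5
  expect_true(all(abs(colMeans(tr)) < 3 * se))
  expect_error(sample_transform(-1, 10), "bounds")
})

test_that("rigid transforms move scenes exactly and invert to identity", {
  sc <- build_iq_scene(20, 2)
  expect_equal(apply_transform(sc, rigid_transform())$meta$sphere_centers,
               sc$meta$sphere_centers)
  tshift <- rigid_transform(translation_mm = c(20, 0, 0))
  sc10 <- build_sphere_scene(10, 5, 1)
  moved <- apply_transform(sc10, tshift)
  expect_equal(moved$compartments[[2]]$shape$center, c(20, 0, 0))
  expect_equal(moved$compartments[[2]]$shape$radius, 5)  # rigid: size unchanged
  tr <- sample_transform(5, 20, seed = 42)
  back <- apply_transform(apply_transform(sc, tr), invert_transform(tr))
  expect_equal(back$meta$sphere_centers, sc$meta$sphere_centers,
               tolerance = 1e-12)
  for (i in seq_along(sc$compartments)) {
    expect_equal(back$compartments[[i]]$shape$center,
                 sc$compartments[[i]]$shape$center, tolerance = 1e-12)
  }
})

test_that("Gaussian blur has unit mass, identity limit and the analytic profile", {
  g <- grid_spec(2, c(11, 11, 11), origin = rep(-11, 3))
  img <- activity_image(array(7, c(11, 11, 11)), g)
  expect_identical(blur_image(img, 0)$values, img$values)
  # uniform field invariant everywhere under replicate padding
  expect_equal(blur_image(img, 6)$values, img$values, tolerance = 1e-12)
  # analytic centre value of a blurred sphere (10 mm, S = 10, B = 1)
  fx <- aligned_sphere_image(10, 10, 1, voxel_mm = 1, fwhm = 7)
  expect_equal(max(fx$image$values), blurred_sphere_center(5, 7, 10, 1),
               tolerance = 0.02)
  # total activity conserved when the object is far from the window edge
  fx0 <- aligned_sphere_image(13, 10, 1, voxel_mm = 1, margin_mm = 25)
  expect_equal(total_activity(blur_image(fx0$image, 7)), total_activity(fx0$image),
               tolerance = 1e-3)
  expect_error(blur_image(img, -1), "fwhm")
})

test_that("resolution modelling sharpens blurred objects and conserves activity", {
  fx <- aligned_sphere_image(22, 20, 2, voxel_mm = 2, fwhm = 7, margin_mm = 16)
  expect_identical(psf_enhance(fx$image, 7, 0)$values, fx$image$values)
  enh <- psf_enhance(fx$image, 7, 10)
  expect_gt(max(enh$values), max(fx$image$values))
  expect_true(all(enh$values >= 0))
  expect_equal(sum(enh$values) / sum(fx$image$values), 1, tolerance = 1e-6)
  expect_error(psf_enhance(fx$image, 0, 5), "kernel_fwhm")
})

test_that("equal-count schedules compensate decay exactly", {
  # no decay: all durations equal the first, exactly
  s0 <- equal_counts_schedule(5, 12, Inf)
  expect_identical(s0$duration, rep(5, 12))
  # second duration against an independent root-finding oracle
  lam <- log(2) / 109.77
  d2 <- uniroot(function(d) exp(-lam * 5) * (1 - exp(-lam * d)) - (1 - exp(-lam * 5)),
                c(4, 7), tol = 1e-12)$root
  s <- equal_counts_schedule(5, 12, 109.77)
  expect_equal(s$duration[2], d2, tolerance = 1e-9)
  expect_equal(round(d2, 2), 5.16)
  # expected counts equal by independent quadrature
  counts <- sapply(seq_len(12), function(k)
    integrate(function(t) exp(-lam * t), s$start[k], s$start[k] + s$duration[k],
              rel.tol = 1e-10)$value)
  expect_lt(diff(range(counts)) / mean(counts), 1e-3)
  # frames contiguous, durations strictly increasing under decay
  expect_equal(s$start[-1], cumsum(s$duration)[-12])
  expect_true(all(diff(s$duration) > 0))
  expect_error(equal_counts_schedule(-1, 12), "first_duration")
  expect_error(equal_counts_schedule(5, 12, -3), "half_life")
  expect_error(equal_counts_schedule(60, 50, 109.77), "infeasible")
})

test_that("count noise is reproducible and follows Poisson scaling", {
  g <- grid_spec(4, c(8, 8, 8), origin = rep(-16, 3))
  img <- activity_image(array(5, c(8, 8, 8)), g)
  sch <- equal_counts_schedule(5, 1)
  n1 <- add_noise(img, noise_model(600, seed = 7), sch)
  n2 <- add_noise(img, noise_model(600, seed = 7), sch)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values,
                         add_noise(img, noise_model(600, seed = 8), sch)$values))
  # quadrupling counts halves the relative noise
  sds <- sapply(c(600, 2400), function(scale) {
    reps <- sapply(1:150, function(i)
      add_noise(img, noise_model(scale, seed = i), sch)$values[1])
    sd(reps)
  })
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.25)
  # quantile-coupled draws have the same marginal spread
  sd_c <- sd(sapply(1:150, function(i)
    add_noise(img, noise_model(600, seed = i), sch, quantile_coupled = TRUE)$values[1]))
  expect_equal(sd_c, sds[1], tolerance = 0.3)
  expect_error(noise_model(0), "counts_per_mL_per_min")
})

test_that("the replicate chain composes and documents its provenance", {
  sc <- build_sphere_scene(17, 20, 2, half_extent = 50)
  g <- grid_spec(4, c(16, 16, 16), origin = rep(-32, 3))
  # negligible blur and unit fine factor: the chain reduces to voxelization
  prof <- recon_profile(g, fwhm = 0.1, fine_factor = 1, label = "ideal")
  img <- simulate_replicate(sc, prof, check_coverage = FALSE)
  ref <- voxelize_scene(sc, g, 4, check_coverage = FALSE)
  expect_equal(img$values, ref$values, tolerance = 1e-12)
  # downsampling from the fine grid conserves total activity
  prof2 <- recon_profile(g, fwhm = 7, fine_factor = 2, label = "TOF-4mm")
  fine <- blur_image(voxelize_scene(sc, refine_grid(g, 2), 4, check_coverage = FALSE), 7)
  coarse <- simulate_replicate(sc, prof2, check_coverage = FALSE)
  expect_equal(total_activity(coarse), total_activity(fine), tolerance = 1e-3)
  expect_equal(coarse$provenance$profile$label, "TOF-4mm")
  expect_equal(coarse$provenance$blur$fwhm, 7)
  # repositioned replicates carry their own distinct transforms
  series <- simulate_sphere_series(10, prof2, "repositioned", n = 3,
                                   master_seed = 5, counts_per_mL_per_min = NULL)
  expect_equal(nrow(series), 3)
})

test_that("a replicate series is bit-reproducible under a fixed master seed", {
  prof <- iq_recon_profiles()[["TOF-4mm"]]
  a <- simulate_sphere_series(13, prof, "repositioned", n = 4, master_seed = 21)
  b <- simulate_sphere_series(13, prof, "repositioned", n = 4, master_seed = 21)
  expect_identical(a, b)
  c2 <- simulate_sphere_series(13, prof, "repositioned", n = 4, master_seed = 22)
  expect_false(identical(a$rc_max, c2$rc_max))
})

test_that("repositioning-induced spread is smallest for SUVpeak", {
  # noiseless repositioned replicates isolate the tissue-fraction and
  # resolution sampling effects; the peak VOI average is the most stable
  # metric, the single maximum voxel the least
  prof <- iq_recon_profiles()[["TOF-4mm"]]
  reps <- simulate_sphere_series(10, prof, "repositioned", n = 60,
                                 master_seed = 31, counts_per_mL_per_min = NULL)
  expect_true(all(reps$ok))
  expect_lt(sd(reps$rc_peak), sd(reps$rc_mean))
  expect_lt(sd(reps$rc_mean), sd(reps$rc_max))
})
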