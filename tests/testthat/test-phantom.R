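# Phantom generator: mask rasterisation, velocity synthesis, determinism.

test_that("rasterised cross-sections match the analytic lumen area", {
  ph <- cached_phantom("TAV")
  cfg <- ph$config
  # end-diastolic frame (area scale 1): slice through the ascending limb
  k_dia <- which.min(ph$truth$area_scale)
  asc <- plane_at(ph$geometry, 0.15)
  iz <- round((asc$origin[3] - cfg$grid$meta$origin[3]) /
                cfg$grid$meta$voxel_spacing[3]) + 1
  # count only the ascending-limb disc (the slice also cuts the descending limb)
  sp <- cfg$grid$meta$voxel_spacing
  sl <- ph$masks[[k_dia]]$labels[, , iz]
  idx <- which(sl == 7L, arr.ind = TRUE)
  w <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
  near <- sqrt((w[, 1] - asc$origin[1])^2 + (w[, 2] - asc$origin[2])^2) <
    0.95 * ph$geometry$arch_radius
  area <- sum(near) * sp[1] * sp[2]
  expect_equal(area, pi * cfg$lumen_radius^2, tolerance = 0.1)
})

test_that("wall pulsation scales the lumen area by the programmed ratio", {
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  ar <- area_curve(ph$masks, "aorta", asc)
  ratio <- max(ar$area_cm2) / min(ar$area_cm2)
  expect_lt(abs(ratio - 1.3), 0.05)
})

test_that("zero area pulsation gives identical masks across frames", {
  cfg <- phantom_config("TAV", area_pulsation = 0)
  geo <- make_geometry(cfg)
  masks <- rasterize_masks(geo, cfg)
  expect_identical(masks[[1]]$labels, masks[[15]]$labels)
})

test_that("swirl-free noise-free phantom has no in-plane velocity", {
  cfg <- phantom_config("TAV", swirl_ratio = 0, noise_sd = 0)
  ph <- generate_phantom(cfg)
  asc <- plane_at(ph$geometry, 0.15)
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc,
                       ph$truth$peak_frame)
  expect_lt(max(abs(smp$u[smp$lumen])), 1e-9)
  expect_lt(max(abs(smp$v[smp$lumen])), 1e-9)
  rm(ph); gc(verbose = FALSE)
})

test_that("TAV secondary flow is a zero-circulation Dean pair", {
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc,
                       ph$truth$peak_frame)
  om <- axial_vorticity(smp)
  ok <- is.finite(om)
  expect_lt(abs(sum(om[ok])), 0.05 * sum(abs(om[ok])))
  # two opposite-sign lobes split by the chord axis
  idx <- which(ok, arr.ind = TRUE)
  qside <- smp$coords2[idx[, 2]] > mean(smp$coords2[idx[, 2]])
  expect_lt(mean(om[ok][qside]) * mean(om[ok][!qside]), 0)
})

test_that("BAV secondary flow has positive net axial vorticity at peak", {
  ph <- cached_phantom("BAV")
  asc <- plane_at(ph$geometry, 0.15)
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc,
                       ph$truth$peak_frame)
  om <- axial_vorticity(smp)
  expect_gt(mean(om[is.finite(om)]), 0)
})

test_that("same seed is bit-identical; seeds differ only in noise", {
  cfg <- phantom_config("TAV", grid = phantom_grid(n_frames = 12),
                        heart_rate = 75)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$velocity$values, b$velocity$values)
  cfg2 <- phantom_config("TAV", grid = phantom_grid(n_frames = 12),
                         heart_rate = 75, seed = 2)
  c2 <- generate_phantom(cfg2)
  expect_false(identical(a$velocity$values, c2$velocity$values))
  expect_identical(a$masks[[3]]$labels, c2$masks[[3]]$labels)
  # deterministic structure cancels in the difference: what remains is the
  # difference of two independent noise fields
  d <- a$velocity$values[, , , 3, ] - c2$velocity$values[, , , 3, ]
  expect_equal(sd(d), sqrt(2) * cfg$noise_sd, tolerance = 0.02)
  expect_lt(abs(mean(d)), 0.05)
  rm(a, b, c2); gc(verbose = FALSE)
})

test_that("synthetic velocities respect the venc after clipping", {
  ph <- cached_phantom("TAV", noise_sd = 5)
  expect_lte(max(abs(ph$velocity$values)), ph$config$grid$meta$venc)
})

test_that("swirl on a sub-resolved lumen is rejected", {
  cfg <- phantom_config("TAV", lumen_radius = 2, aortic_length = 60)
  expect_error(generate_phantom(cfg), "3 voxels")
})

test_that("phantom truth integrates to the programmed stroke volume", {
  ph <- cached_phantom("TAV")
  expect_equal(net_volume(ph$truth$waveform), ph$truth$stroke_volume,
               tolerance = 0.005)
})
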