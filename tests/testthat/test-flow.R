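# Flux, volumes, cardiac output, kinetic energy.

test_that("uniform through-plane flow gives the closed-form flux", {
  st <- straight_tube(vz = 10)  # 100 voxels of 1 mm^2 at 10 cm/s
  expect_equal(plane_flux(st$field, st$mask, "aorta", st$plane, 1), 10)
})

test_that("trilinear plane sampling agrees with the nearest-voxel gather", {
  st <- straight_tube(vz = 10)
  expect_equal(plane_flux(st$field, st$mask, "aorta", st$plane, 1,
                          method = "trilinear"), 10, tolerance = 0.03)
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  k <- ph$truth$peak_frame
  expect_equal(plane_flux(ph$velocity, ph$masks, "aorta", asc, k, "trilinear"),
               plane_flux(ph$velocity, ph$masks, "aorta", asc, k, "nearest"),
               tolerance = 0.05)
})

test_that("velocity perpendicular to the normal carries no flux", {
  st <- straight_tube(vz = 0, vx = 25, vy = -10)
  expect_equal(plane_flux(st$field, st$mask, "aorta", st$plane, 1), 0)
})

test_that("flux is linear in the field and odd under normal flip", {
  st <- straight_tube(vz = 8, vx = 3)
  st2 <- straight_tube(vz = 16, vx = 6)
  f1 <- plane_flux(st$field, st$mask, "aorta", st$plane, 1)
  f2 <- plane_flux(st2$field, st2$mask, "aorta", st2$plane, 1)
  expect_equal(f2, 2 * f1)
  flipped <- analysis_plane(st$plane$origin, -st$plane$normal)
  expect_equal(plane_flux(st$field, st$mask, "aorta", flipped, 1), -f1)
})

test_that("plane-mean velocity equals flux over lumen area", {
  set.seed(11)
  dims <- c(12, 12, 6)
  meta <- grid_meta(c(1, 1, 1), 4, frame_interval = 40)
  arr <- array(rnorm(prod(dims) * 4 * 3, sd = 15), dim = c(dims, 4, 3))
  lab <- array(0L, dims); lab[3:10, 3:10, ] <- 7L
  vf <- velocity_field(arr, meta); mk <- label_mask(lab, meta)
  pl <- analysis_plane(c(5.5, 5.5, 3), c(0, 0, 1))
  pmv <- plane_mean_velocity(vf, mk, "aorta", pl)
  for (k in 1:4) {
    flux <- plane_flux(vf, mk, "aorta", pl, k)
    expect_equal(pmv$curve$mean_velocity_cm_s[k],
                 flux / pmv$curve$lumen_area_cm2[k])
  }
  # steady uniform field: temporal sd of the mean is zero
  st <- straight_tube(vz = 60)
  pm <- plane_mean_velocity(st$field, st$mask, "aorta", st$plane)
  expect_equal(pm$peak_cm_s, 60)
  expect_equal(pm$temporal_sd_cm_s, 0)
})

test_that("volumes and regurgitant fraction follow their definitions", {
  t <- seq(0, 950, by = 50)
  pos <- flow_curve(t, rep(10, 20))
  expect_equal(regurgitant_fraction(pos), 0)
  # forward 100 mL, backward 1.5 mL -> rf 1.5 %
  q <- c(rep(200, 10), rep(-6, 5), rep(0, 5))  # 100 mL fwd, 1.5 mL bwd
  crv <- flow_curve(t, q)
  expect_equal(forward_volume(crv), 100)
  expect_equal(backward_volume(crv), 1.5)
  expect_equal(regurgitant_fraction(crv), 1.5)
  expect_equal(net_volume(crv), 98.5)
  zero <- flow_curve(t, rep(-1, 20))
  expect_error(regurgitant_fraction(zero), "forward volume")
})

test_that("cardiac output reproduces the clinical arithmetic", {
  expect_equal(round(cardiac_output(67, 70), 1), 4.7)
  expect_equal(round(cardiac_output(108, 47), 1), 5.1)
  expect_equal(cardiac_output(1000, 1), 1.0)
  expect_error(cardiac_output(0, 70), "> 0")
})

test_that("kinetic energy has the closed form, scaling and positivity", {
  # 100 voxels of 1 mm^3 at 1 m/s, rho 1060 -> 0.053 mJ
  dims <- c(14, 14, 1)
  meta <- grid_meta(c(1, 1, 1), 1, frame_interval = 30)
  arr <- array(0, dim = c(dims, 1, 3))
  lab <- array(0L, dims); lab[3:12, 3:12, 1] <- 7L
  arr[3:12, 3:12, 1, 1, 3] <- 100  # 1 m/s
  vf <- velocity_field(arr, meta); mk <- label_mask(lab, meta)
  expect_equal(kinetic_energy(vf, mk, "aorta", 1), 0.053)
  # zero field
  vf0 <- velocity_field(array(0, dim = c(dims, 1, 3)), meta)
  expect_equal(kinetic_energy(vf0, mk, "aorta", 1), 0)
  # doubling the velocity quadruples the energy
  vf2 <- velocity_field(arr * 2, meta)
  expect_equal(kinetic_energy(vf2, mk, "aorta", 1),
               4 * kinetic_energy(vf, mk, "aorta", 1))
  # KE >= 0 on random fields
  set.seed(3)
  arrr <- array(rnorm(prod(dims) * 3, sd = 40), dim = c(dims, 1, 3))
  expect_gte(kinetic_energy(velocity_field(arrr, meta), mk, "aorta", 1), 0)
})

test_that("phantom peak flux matches the programmed waveform peak", {
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  crv <- compute_flow_curve(ph$velocity, ph$masks, "aorta", asc)
  expect_equal(max(crv$flux_ml_s), max(ph$truth$waveform$flux_ml_s),
               tolerance = 0.03)
  # plane-mean peak close to the programmed profile mean
  pmv <- plane_mean_velocity(ph$velocity, ph$masks, "aorta", asc)
  expect_equal(pmv$peak_cm_s,
               max(crv$flux_ml_s) / pmv$curve$lumen_area_cm2[which.max(crv$flux_ml_s)],
               tolerance = 0.05)
})
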