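# Plane extraction, vorticity, chord profiles, shear, OSI.

test_that("uniform axial flow extracts as pure through-plane velocity", {
  st <- straight_tube(vz = 60)
  smp <- extract_plane(st$field, st$mask, "aorta", st$plane, 1)
  lum <- smp$lumen
  expect_equal(max(abs(smp$w[lum] - 60)), 0, tolerance = 1e-9)
  expect_lt(max(abs(smp$u[lum])), 1e-9)
  expect_lt(max(abs(smp$v[lum])), 1e-9)
})

test_that("rigid rotation extracts as in-plane speed Omega * r", {
  dims <- c(30, 30, 6)
  meta <- grid_meta(c(1, 1, 1), 1, frame_interval = 30)
  omega <- 10  # 1/s
  ctr <- c(15.5, 15.5)
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2])
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2
  arr <- array(0, dim = c(dims, 1, 3))
  lab <- array(0L, dims)
  for (z in 1:dims[3]) {
    vx <- matrix(-omega * (g$y - ctr[2]) / 10, dims[1], dims[2])  # cm/s
    vy <- matrix(omega * (g$x - ctr[1]) / 10, dims[1], dims[2])
    arr[, , z, 1, 1] <- vx
    arr[, , z, 1, 2] <- vy
    lab[, , z] <- matrix(ifelse(r2 <= 10^2, 7L, 0L), dims[1], dims[2])
  }
  vf <- velocity_field(arr, meta); mk <- label_mask(lab, meta)
  pl <- analysis_plane(c(ctr - 1, 3), c(0, 0, 1), c(1, 0, 0))
  smp <- extract_plane(vf, mk, "aorta", pl, 1)
  lum <- smp$lumen & !is.na(smp$u)
  idx <- which(lum, arr.ind = TRUE)
  r_mm <- sqrt(smp$coords1[idx[, 1]]^2 + smp$coords2[idx[, 2]]^2)
  spd <- sqrt(smp$u[lum]^2 + smp$v[lum]^2)  # cm/s
  keep <- r_mm > 2
  expect_equal(spd[keep], omega * r_mm[keep] / 10, tolerance = 1e-6)
  expect_lt(max(abs(smp$w[lum])), 1e-9)
  # solid-body rotation has vorticity 2 * Omega in the interior
  om <- axial_vorticity(smp)
  interior <- lum & !is.na(om)
  idx2 <- which(interior, arr.ind = TRUE)
  rin <- sqrt(smp$coords1[idx2[, 1]]^2 + smp$coords2[idx2[, 2]]^2) < 7
  expect_lt(max(abs(om[interior][rin] - 2 * omega)), 0.005 * 2 * omega)
})

test_that("uniform in-plane flow is irrotational", {
  smp <- make_plane_sample(function(p, q) 25 + 0 * p,
                           function(p, q) -10 + 0 * p,
                           function(p, q) 0 * p)
  om <- axial_vorticity(smp)
  expect_lt(max(abs(om[is.finite(om)])), 1e-9)
})

test_that("plane energy matches direct voxel sampling", {
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  k <- ph$truth$peak_frame
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc, k)
  e_interp <- mean(smp$u[smp$lumen]^2 + smp$v[smp$lumen]^2 + smp$w[smp$lumen]^2)
  # direct nearest-voxel gather over the same plane slab
  m <- ph$masks[[k]]
  idx <- which(m$labels == 7L, arr.ind = TRUE)
  w <- cbind((idx[, 1] - 1) * m$meta$voxel_spacing[1],
             (idx[, 2] - 1) * m$meta$voxel_spacing[2],
             (idx[, 3] - 1) * m$meta$voxel_spacing[3])
  rel <- sweep(w, 2, asc$origin, "-")
  d <- rel %*% asc$normal
  r_in <- sqrt(rowSums(rel^2) - d^2)
  sel <- abs(d) <= sum(abs(asc$normal) * m$meta$voxel_spacing) / 2 &
    r_in <= asc$radius
  vm <- sapply(1:3, function(c) ph$velocity$values[, , , k, c][idx[sel, ]])
  e_direct <- mean(rowSums(vm^2))
  expect_equal(e_interp, e_direct, tolerance = 0.03)
})

test_that("a symmetric parabolic jet yields a symmetric chord profile", {
  R <- 10
  smp <- make_plane_sample(function(p, q) 0 * p, function(p, q) 0 * p,
                           function(p, q) 100 * pmax(1 - (p^2 + q^2) / R^2, 0),
                           R = R, res = 0.1)
  ch <- chord_profile(smp, n_points = 101)
  expect_equal(ch$w_cm_s, rev(ch$w_cm_s), tolerance = 0.02)
  expect_equal(ch$x_norm[which.max(ch$w_cm_s)], 0.5, tolerance = 0.05)
  expect_true(all(diff(ch$x_norm) > 0))
})

test_that("the phantom top-hat jet has a flat central plateau", {
  ph <- cached_phantom("TAV")
  asc <- plane_at(ph$geometry, 0.15)
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc,
                       ph$truth$peak_frame)
  ch <- chord_profile(smp)
  mid <- ch$w_cm_s[ch$x_norm >= 0.25 & ch$x_norm <= 0.75]
  expect_gt(min(mid), 0.98 * max(ch$w_cm_s))
})

test_that("the BAV jet is skewed toward the convex wall", {
  ph <- cached_phantom("BAV")
  asc <- plane_at(ph$geometry, 0.15)
  smp <- extract_plane(ph$velocity, ph$masks, "aorta", asc,
                       ph$truth$peak_frame)
  ch <- chord_profile(smp)
  expect_lt(ch$x_norm[which.max(ch$w_cm_s)], 0.3)
})

test_that("Poiseuille flow has the closed-form wall shear", {
  U <- 100; R <- 10; mu <- 3.5e-3  # 1 m/s, 1 cm, Pa s
  smp <- make_plane_sample(function(p, q) 0 * p, function(p, q) 0 * p,
                           function(p, q) U * pmax(1 - (p^2 + q^2) / R^2, 0),
                           R = R, res = 0.05)
  ch <- shear_profile(chord_profile(smp, n_points = 201))
  tau_wall <- 2 * mu * (U / 100) / (R / 1000)  # 0.7 Pa
  expect_equal(abs(ch$tau_ax_pa[1]), tau_wall, tolerance = 0.02)
  expect_equal(abs(ch$tau_ax_pa[nrow(ch)]), tau_wall, tolerance = 0.02)
  # constant velocity along the chord -> zero shear
  flat <- make_plane_sample(function(p, q) 0 * p, function(p, q) 0 * p,
                            function(p, q) 42 + 0 * p, R = R, res = 0.1)
  chf <- shear_profile(chord_profile(flat))
  expect_lt(max(abs(chf$tau_ax_pa)), 1e-9)
})

test_that("a swirl-free phantom has negligible tangential shear", {
  cfg <- phantom_config("TAV", swirl_ratio = 0, noise_sd = 0)
  ph <- generate_phantom(cfg)
  asc <- plane_at(ph$geometry, 0.15)
  ch <- shear_profile(chord_profile(
    extract_plane(ph$velocity, ph$masks, "aorta", asc, ph$truth$peak_frame)))
  expect_lt(max(abs(ch$tau_tan_pa)), 0.01 * max(abs(ch$tau_ax_pa)))
  rm(ph); gc(verbose = FALSE)
})

test_that("OSI is 0 for unidirectional and 0.5 for zero-mean shear", {
  expect_equal(osi(c(1, 2, 0.5, 3)), 0)
  expect_equal(osi(sin(2 * pi * (0:19) / 20)), 0.5)
  expect_equal(osi(rep(0, 10)), 0)
  # bounded and invariant under positive rescaling
  set.seed(9)
  for (i in 1:20) {
    tau <- rnorm(24)
    expect_gte(osi(tau), 0)
    expect_lte(osi(tau), 0.5)
    expect_equal(osi(tau), osi(3.7 * tau))
  }
  # matrix input: one OSI per column
  m <- cbind(abs(rnorm(12)), sin(2 * pi * (0:11) / 12))
  expect_equal(unname(osi(m)), c(0, 0.5), tolerance = 1e-9)
})

test_that("discrete circulation matches the vorticity integral (Stokes)", {
  # Lamb-Oseen-like vortex sampled on a lattice
  G <- 500; sig <- 3
  uth <- function(r) G * (1 - exp(-r^2 / (2 * sig^2))) / pmax(r, 1e-9)
  smp <- make_plane_sample(
    function(p, q) -q / pmax(sqrt(p^2 + q^2), 1e-9) * uth(sqrt(p^2 + q^2)),
    function(p, q) p / pmax(sqrt(p^2 + q^2), 1e-9) * uth(sqrt(p^2 + q^2)),
    function(p, q) 0 * p, R = 12, res = 0.2)
  om <- axial_vorticity(smp)
  r0 <- 8  # integration disc well inside the lumen
  idx <- which(is.finite(om), arr.ind = TRUE)
  rr <- sqrt(smp$coords1[idx[, 1]]^2 + smp$coords2[idx[, 2]]^2)
  dA <- (smp$spacing / 1000)^2
  circ_from_omega <- sum(om[idx][rr <= r0]) * dA
  # line integral of the in-plane velocity around the circle, by bilinear
  # interpolation at dense points (independent quadrature route)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  px <- r0 * cos(th); py <- r0 * sin(th)
  pii <- (px - smp$coords1[1]) / smp$spacing + 1
  pjj <- (py - smp$coords2[1]) / smp$spacing + 1
  bil <- function(mat) {
    x0 <- floor(pii); y0 <- floor(pjj); fx <- pii - x0; fy <- pjj - y0
    mat[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      mat[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      mat[cbind(x0, y0 + 1)] * (1 - fx) * fy +
      mat[cbind(x0 + 1, y0 + 1)] * fx * fy
  }
  u <- bil(smp$u) / 100; v <- bil(smp$v) / 100  # m/s
  tx <- -sin(th); ty <- cos(th)
  dl <- 2 * pi * (r0 / 1000) / length(th)
  circ_line <- sum((u * tx + v * ty)) * dl
  expect_equal(circ_from_omega, circ_line, tolerance = 0.03)
})
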