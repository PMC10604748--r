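# Synthetic TAV/BAV aorta flow phantom.
#
# The phantom is a kinematic construction, not a CFD solution: the axial jet
# is a waveform-scaled top-hat profile with a linear boundary-layer ramp,
# delayed along the centreline by arclength / PWV; secondary flow is a
# stream-function vortex model (mirrored Dean pair for TAV, a single
# off-centre counter-clockwise vortex for BAV); wall pulsation rescales the
# lumen radius by sqrt(A(t)/A0). Everything downstream of the generator
# treats the result as a measurement.

bav_skew_strength <- 0.8   # linear jet skew toward the convex wall (BAV)
bav_vortex_center <- -0.4  # vortex centre on the convex->concave axis
bav_vortex_sigma <- 0.2    # Lamb-Oseen core size (lumen-radius units)

# Axial jet profile: top-hat with a linear near-wall ramp of relative
# thickness b; rho is radius in lumen-radius units.
jet_profile <- function(rho, b) pmin(1, pmax(0, (1 - rho) / b))

# Linear skew factor toward the convex wall (P = +1); integrates to 1 over
# the disc so the flux scaling is unaffected.
jet_skew <- function(P, strength) 1 + strength * pmax(pmin(P, 1), -1) / 2

# In-plane (secondary-flow) velocity models on the unit disc, in local
# convex (P) / binormal (Q) coordinates. TAV: a mirrored Dean-like vortex
# pair from a stream function odd in Q (zero net circulation, velocity
# vanishing at the wall). BAV: a Lamb-Oseen vortex centred toward the
# concave wall, whose axial vorticity is positive everywhere, giving the
# positive net circulation (counter-clockwise helical flow) that
# characterises the right-left fusion jet.
swirl_velocity <- function(P, Q, mode) {
  rho2 <- P^2 + Q^2
  inside <- rho2 < 1
  if (mode == "TAV") {
    B <- pmax(1 - rho2, 0)
    uP <- (B^2 - 4 * Q^2 * B)
    uQ <- 4 * P * Q * B
  } else {
    s2 <- bav_vortex_sigma^2
    dp <- P - bav_vortex_center
    rc2 <- pmax(dp^2 + Q^2, 1e-12)
    g <- (1 - exp(-rc2 / (2 * s2))) / rc2  # u_theta / rho_c
    uP <- -Q * g
    uQ <- dp * g
  }
  uP[!inside] <- 0; uQ[!inside] <- 0
  list(uP = uP, uQ = uQ)
}

# Peak in-plane speed of each swirl model on the unit disc (for amplitude
# normalisation); computed once per session.
swirl_norm <- local({
  cache <- list()
  function(mode) {
    if (is.null(cache[[mode]])) {
      g <- seq(-1, 1, length.out = 201)
      gr <- expand.grid(P = g, Q = g)
      u <- swirl_velocity(gr$P, gr$Q, mode)
      cache[[mode]] <<- max(sqrt(u$uP^2 + u$uQ^2))
    }
    cache[[mode]]
  }
})

# Precompute, for every voxel that can ever lie in the lumen, its nearest
# centreline point and local cylindrical coordinates:
#   s     arclength of the nearest centreline point (mm)
#   p, q  in-plane offsets along the convex / binormal axes (mm)
#   r     in-plane radial distance (mm)
# plus the local frame vectors needed to compose velocity vectors.
lumen_geometry_table <- function(geometry, config) {
  meta <- config$grid$meta
  dims <- config$grid$dim
  sp <- meta$voxel_spacing
  r_max <- config$lumen_radius * sqrt(1 + config$area_pulsation) + max(sp)

  P <- geometry$centerline
  lo <- pmax(floor((apply(P, 2, min) - r_max) / sp) + 1, 1)
  hi <- pmin(ceiling((apply(P, 2, max) + r_max) / sp) + 1, dims)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]

  n_cl <- nrow(P)
  cl_sq <- rowSums(P^2)
  rows <- list(); nr <- 0
  for (kz in iz) {
    vox <- as.matrix(expand.grid(ix = ix, iy = iy, iz = kz))
    w <- voxel_to_world(vox, meta)
    d2 <- outer(rowSums(w^2), cl_sq, "+") - 2 * (w %*% t(P))
    k <- max.col(-d2, ties.method = "first")
    rel <- w - P[k, , drop = FALSE]
    tg <- geometry$tangent[k, , drop = FALSE]
    ex <- geometry$convex_dir[k, , drop = FALSE]
    ey <- cbind(tg[, 2] * ex[, 3] - tg[, 3] * ex[, 2],
                tg[, 3] * ex[, 1] - tg[, 1] * ex[, 3],
                tg[, 1] * ex[, 2] - tg[, 2] * ex[, 1])
    p <- rowSums(rel * ex)
    q <- rowSums(rel * ey)
    r <- sqrt(p^2 + q^2)
    keep <- r <= r_max
    if (!any(keep)) next
    nr <- nr + 1
    rows[[nr]] <- list(vox = vox[keep, , drop = FALSE],
                       s = geometry$arclength[k[keep]],
                       p = p[keep], q = q[keep], r = r[keep],
                       tangent = tg[keep, , drop = FALSE],
                       ex = ex[keep, , drop = FALSE],
                       ey = ey[keep, , drop = FALSE])
  }
  if (nr == 0) abort("empty lumen: geometry does not intersect the grid.")
  list(vox = do.call(rbind, lapply(rows, `[[`, "vox")),
       s = unlist(lapply(rows, `[[`, "s")),
       p = unlist(lapply(rows, `[[`, "p")),
       q = unlist(lapply(rows, `[[`, "q")),
       r = unlist(lapply(rows, `[[`, "r")),
       tangent = do.call(rbind, lapply(rows, `[[`, "tangent")),
       ex = do.call(rbind, lapply(rows, `[[`, "ex")),
       ey = do.call(rbind, lapply(rows, `[[`, "ey")))
}

# Ellipsoidal left-ventricle blob below the aortic root (for evaluation-plane
# and segmentation-metric logic; not scaled to anatomical LV volume).
lv_blob_indices <- function(geometry, config) {
  meta <- config$grid$meta
  dims <- config$grid$dim
  centre <- geometry$centerline[1, ] - c(0, 0, 18 + 16)
  semi <- c(14, 14, 16)
  lo <- pmax(floor((centre - semi) / meta$voxel_spacing) + 1, 1)
  hi <- pmin(ceiling((centre + semi) / meta$voxel_spacing) + 1, dims)
  vox <- as.matrix(expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3]))
  w <- voxel_to_world(vox, meta)
  d <- sweep(w, 2, centre, "-")
  inside <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 <= 1
  vox[inside, , drop = FALSE]
}

#' Rasterise phantom masks for every cardiac phase
#'
#' Labels a voxel as aorta when its in-plane distance to the centreline is
#' within the lumen radius scaled by `sqrt(A(t)/A0)` for that frame, and adds
#' an ellipsoidal left-ventricle blob (constant across frames).
#'
#' @param geometry An [make_geometry()] result.
#' @param config The [phantom_config()] providing the grid and lumen radius.
#' @param area_scale Per-frame relative lumen area `A(t)/A0` (length
#'   `n_frames`); 1 everywhere gives identical masks across frames.
#' @param lumen Optional precomputed lumen geometry table (internal reuse).
#' @return A list of [label_mask()], one per frame.
#' @export
rasterize_masks <- function(geometry, config, area_scale = NULL, lumen = NULL) {
  meta <- config$grid$meta
  dims <- config$grid$dim
  n_frames <- meta$n_frames
  area_scale <- area_scale %||% rep(1, n_frames)
  if (length(area_scale) != n_frames)
    abort("`area_scale` must have one value per frame.")
  lumen <- lumen %||% lumen_geometry_table(geometry, config)
  vocab <- aorta_vocabulary()
  lv <- lv_blob_indices(geometry, config)
  lin_lumen <- lumen$vox[, 1] + dims[1] * (lumen$vox[, 2] - 1) +
    dims[1] * dims[2] * (lumen$vox[, 3] - 1)
  lin_lv <- lv[, 1] + dims[1] * (lv[, 2] - 1) + dims[1] * dims[2] * (lv[, 3] - 1)
  lapply(seq_len(n_frames), function(k) {
    R_k <- config$lumen_radius * sqrt(area_scale[k])
    labels <- array(0L, dim = dims)
    labels[lin_lv] <- vocab[["LV"]]
    inside <- lumen$r <= R_k
    if (!any(inside)) abort(sprintf("empty lumen at frame %d.", k))
    labels[lin_lumen[inside]] <- vocab[["aorta"]]
    label_mask(labels, grid_meta(meta$voxel_spacing, 1L, meta$frame_interval,
                                 meta$venc, meta$origin), vocab)
  })
}

# Discrete effective lumen area (cm^2) of the jet profile on a reference
# cross-section slab, per frame: what divides the waveform so the programmed
# flux is reproduced on this voxel grid.
effective_area <- function(lumen, config, area_scale, s_ref) {
  sp <- config$grid$meta$voxel_spacing
  b <- config$boundary_layer_fraction
  skew <- if (config$valve_mode == "BAV") bav_skew_strength else 0
  slab <- sp[3]  # reference section sits on the vertical ascending limb
  sel <- abs(lumen$s - s_ref) <= slab / 2
  if (!any(sel)) abort("reference cross-section contains no lumen voxels.")
  a_vox_cm2 <- sp[1] * sp[2] / 100
  vapply(area_scale, function(sc) {
    R_k <- config$lumen_radius * sqrt(sc)
    rho <- lumen$r[sel] / R_k
    w <- jet_profile(rho, b) * jet_skew(lumen$p[sel] / R_k, skew)
    axial <- lumen$tangent[sel, 3]  # plane normal is +z on the ascending limb
    sum(w * axial) * a_vox_cm2
  }, numeric(1))
}

#' Synthesise the phantom velocity field
#'
#' Composes, at every lumen voxel and frame: an axial top-hat jet scaled so
#' the programmed flux waveform (delayed by arclength / PWV) is reproduced on
#' the discrete grid; mode-specific secondary flow with peak in-plane speed
#' `swirl_ratio` times the local peak axial speed; additive Gaussian noise
#' (seeded); and per-component clipping at the venc with a clipped-voxel
#' count recorded in attribute `n_clipped`.
#'
#' @inheritParams rasterize_masks
#' @param truth A `phantom_truth` from [generate_phantom()] internals (the
#'   programmed waveform and per-frame area scale).
#' @return A [velocity_field()].
#' @export
synthesize_velocity <- function(geometry, config, truth, lumen = NULL) {
  meta <- config$grid$meta
  dims <- config$grid$dim
  n_frames <- meta$n_frames
  sp <- meta$voxel_spacing
  b <- config$boundary_layer_fraction
  if (config$swirl_ratio > 0 && config$lumen_radius / min(sp) < 3)
    abort("swirl requested with a lumen radius below 3 voxels.")
  lumen <- lumen %||% lumen_geometry_table(geometry, config)
  wf <- truth$waveform
  qfun <- waveform_fun(truth$waveform_spec)
  area_scale <- truth$area_scale
  skew <- if (config$valve_mode == "BAV") bav_skew_strength else 0
  s_ref <- 0.15 * config$aortic_length
  A_eff <- effective_area(lumen, config, area_scale, s_ref)

  lin <- lumen$vox[, 1] + dims[1] * (lumen$vox[, 2] - 1) +
    dims[1] * dims[2] * (lumen$vox[, 3] - 1)
  nvox3 <- prod(dims)
  values <- array(0, dim = c(dims, n_frames, 3))
  set.seed(config$seed)
  n_clipped <- 0L
  norm <- if (config$swirl_ratio > 0) swirl_norm(config$valve_mode) else 1
  for (k in seq_len(n_frames)) {
    t_k <- wf$time_ms[k]
    R_k <- config$lumen_radius * sqrt(area_scale[k])
    inside <- lumen$r <= R_k
    td <- t_k - lumen$s[inside] / config$pwv  # pwv m/s == mm/ms
    Q <- qfun(td)
    rho <- lumen$r[inside] / R_k
    P <- lumen$p[inside] / R_k
    Qc <- lumen$q[inside] / R_k
    W <- (Q / A_eff[k]) * jet_profile(rho, b) * jet_skew(P, skew)  # cm/s
    v <- lumen$tangent[inside, , drop = FALSE] * W
    if (config$swirl_ratio > 0) {
      amp <- config$swirl_ratio * abs(Q) / A_eff[k] / norm
      sw <- swirl_velocity(P, Qc, config$valve_mode)
      v <- v + lumen$ex[inside, , drop = FALSE] * (amp * sw$uP) +
               lumen$ey[inside, , drop = FALSE] * (amp * sw$uQ)
    }
    frame <- matrix(rnorm(nvox3 * 3L, sd = config$noise_sd), nvox3, 3)
    idx <- lin[inside]
    frame[idx, ] <- frame[idx, ] + v
    over <- abs(frame) > meta$venc
    n_clipped <- n_clipped + sum(over)
    frame[over] <- sign(frame[over]) * meta$venc
    values[, , , k, ] <- frame
  }
  out <- velocity_field(values, meta)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a complete synthetic 4-D flow dataset
#'
#' Runs waveform design, geometry construction, mask rasterisation and
#' velocity synthesis, returning the dataset together with the programmed
#' ground truth for parameter-recovery testing. The same seed yields a
#' bit-identical dataset; different seeds differ only in the noise.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_dataset` list: `velocity` ([velocity_field()]), `masks`
#'   (list of [label_mask()] per frame), `geometry`, `truth` (programmed
#'   parameters, waveform and per-frame area scale) and `config`.
#' @export
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config("TAV", noise_sd = 0))
#' ph$truth$stroke_volume
#' }
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) abort("`config` must be a phantom_config.")
  spec <- waveform_spec(config$heart_rate, config$stroke_volume,
                        config$regurgitant_fraction, config$grid$meta$n_frames)
  n_fr <- config$grid$meta$n_frames
  wf <- flow_curve((seq_len(n_fr) - 1) * spec$period / n_fr,
                   waveform_fun(spec)((seq_len(n_fr) - 1) * spec$period / n_fr),
                   period_ms = spec$period)
  wnorm <- pmax(wf$flux_ml_s, 0) / max(wf$flux_ml_s)
  area_scale <- 1 + config$area_pulsation * wnorm
  truth <- structure(
    list(valve_mode = config$valve_mode,
         heart_rate = config$heart_rate,
         stroke_volume = config$stroke_volume,
         regurgitant_fraction = config$regurgitant_fraction,
         aortic_length = config$aortic_length,
         pwv = config$pwv,
         area_pulsation = config$area_pulsation,
         cardiac_output = cardiac_output(config$stroke_volume, config$heart_rate),
         waveform = wf,
         waveform_spec = spec,
         area_scale = area_scale,
         peak_frame = which.max(wf$flux_ml_s)),
    class = "phantom_truth")
  geometry <- make_geometry(config)
  lumen <- lumen_geometry_table(geometry, config)
  masks <- rasterize_masks(geometry, config, area_scale, lumen = lumen)
  velocity <- synthesize_velocity(geometry, config, truth, lumen = lumen)
  structure(list(velocity = velocity, masks = masks, geometry = geometry,
                 truth = truth, config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %s phantom, seed %d\n",
              x$config$valve_mode, x$config$seed))
  print(x$velocity)
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Writes NIfTI velocity components, per-frame masks and a `truth.json` of
#' the programmed parameters into a directory.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_velocity(phantom$velocity, file.path(dir, "velocity"))
  for (k in seq_along(phantom$masks))
    write_mask(phantom$masks[[k]], file.path(dir, sprintf("mask_%02d.nii.gz", k)))
  truth <- unclass(phantom$truth)
  truth$waveform <- list(time_ms = phantom$truth$waveform$time_ms,
                         flux_ml_s = phantom$truth$waveform$flux_ml_s)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
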