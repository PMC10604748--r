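# Short-axis plane analysis: in-plane velocity decomposition, axial
# vorticity, wall-to-wall chord profiles, shear stress and OSI.

# Bilinear interpolation on a 2-D lattice at continuous 1-based indices.
bilinear <- function(mat, pi_, pj) {
  d <- dim(mat)
  inside <- pi_ >= 1 & pi_ <= d[1] & pj >= 1 & pj <= d[2]
  out <- rep(NA_real_, length(pi_))
  if (!any(inside)) return(out)
  x <- pi_[inside]; y <- pj[inside]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  fx <- x - x0; fy <- y - y0
  idx <- function(i, j) (j - 1) * d[1] + i
  out[inside] <- mat[idx(x0, y0)] * (1 - fx) * (1 - fy) +
    mat[idx(x0 + 1, y0)] * fx * (1 - fy) +
    mat[idx(x0, y0 + 1)] * (1 - fx) * fy +
    mat[idx(x0 + 1, y0 + 1)] * fx * fy
  out
}

#' Interpolate a velocity field onto a short-axis plane lattice
#'
#' Velocities are sampled trilinearly onto a square in-plane lattice and
#' decomposed into the through-plane component `w = v . normal` and the
#' in-plane components `(u, v)` along the plane axes. The lumen indicator is
#' the nearest-voxel mask label.
#'
#' @inheritParams plane_flux
#' @param resolution In-plane lattice spacing in mm (default: finest voxel
#'   spacing).
#' @param half_width Lattice half-extent in mm (default: fitted to the lumen
#'   on the plane plus a margin).
#' @return A `plane_sample` list: matrices `u`, `v`, `w` (cm/s) indexed
#'   \[axis1, axis2\], logical `lumen`, `coords1`/`coords2` (mm offsets along
#'   the axes), `spacing`, `plane`, `frame`.
#' @export
extract_plane <- function(field, mask, label, plane, frame,
                          resolution = NULL, half_width = NULL) {
  m <- mask_for_frame(mask, frame)
  check_paired(field, m)
  meta <- field$meta
  res <- resolution %||% min(meta$voxel_spacing)
  if (is.null(half_width)) {
    pv <- plane_voxels(m, label, plane)  # errors if the plane misses the lumen
    w <- voxel_to_world(pv$idx, m$meta)
    rel <- sweep(w, 2, plane$origin, "-")
    half_width <- max(abs(cbind(rel %*% plane$axis1, rel %*% plane$axis2))) + 2 * res
  }
  g <- seq(-half_width, half_width, by = res)
  ni <- length(g)
  gg <- expand.grid(p = g, q = g)
  world <- matrix(plane$origin, nrow(gg), 3, byrow = TRUE) +
    outer(gg$p, plane$axis1) + outer(gg$q, plane$axis2)
  vox <- world_to_voxel(world, meta)
  comps <- lapply(1:3, function(c)
    trilinear(field$values[, , , frame, c, drop = TRUE], vox, fill = 0))
  vmat <- do.call(cbind, comps)
  id <- resolve_label(m, label)
  lum <- nearest_voxel(m$labels, vox, fill = 0) == id
  shape <- function(x) matrix(x, ni, ni)
  out <- list(u = shape(vmat %*% plane$axis1),
              v = shape(vmat %*% plane$axis2),
              w = shape(vmat %*% plane$normal),
              lumen = shape(lum),
              coords1 = g, coords2 = g, spacing = res,
              plane = plane, frame = frame)
  if (!any(out$lumen)) abort("plane does not intersect the labelled lumen.")
  class(out) <- "plane_sample"
  out
}

#' @export
print.plane_sample <- function(x, ...) {
  cat(sprintf("<plane_sample> %d x %d lattice @ %.2f mm, %d lumen points, frame %d\n",
              nrow(x$w), ncol(x$w), x$spacing, sum(x$lumen), x$frame))
  invisible(x)
}

# Masked partial derivative of a 2-D field along dimension 1 or 2: central
# differences where both neighbours are in the lumen, one-sided at the lumen
# boundary, NA outside.
masked_deriv <- function(f, lumen, h, dim) {
  shift <- function(mat, by) {
    out <- matrix(NA, nrow(mat), ncol(mat))
    if (dim == 1) {
      if (by > 0) out[1:(nrow(mat) - by), ] <- mat[(1 + by):nrow(mat), ]
      else out[(1 - by):nrow(mat), ] <- mat[1:(nrow(mat) + by), ]
    } else {
      if (by > 0) out[, 1:(ncol(mat) - by)] <- mat[, (1 + by):ncol(mat)]
      else out[, (1 - by):ncol(mat)] <- mat[, 1:(ncol(mat) + by)]
    }
    out
  }
  fp <- shift(f, 1L); fm <- shift(f, -1L)
  lp <- shift(lumen, 1L); lm <- shift(lumen, -1L)
  lp[is.na(lp)] <- FALSE; lm[is.na(lm)] <- FALSE
  g <- matrix(NA_real_, nrow(f), ncol(f))
  both <- lumen & lp & lm
  g[both] <- (fp[both] - fm[both]) / (2 * h)
  fwd <- lumen & lp & !lm
  g[fwd] <- (fp[fwd] - f[fwd]) / h
  bwd <- lumen & !lp & lm
  g[bwd] <- (f[bwd] - fm[bwd]) / h
  g
}

#' Axial vorticity of a plane sample
#'
#' The through-plane component of vorticity,
#' \eqn{\omega = \partial v / \partial x - \partial u / \partial y}, by
#' central differences (one-sided at the lumen boundary). Positive values are
#' counter-clockwise about the plane normal (the flow direction).
#'
#' @param sample A [extract_plane()] result (lattice at least 3 x 3).
#' @return Matrix of vorticity in 1/s (`NA` outside the lumen).
#' @export
axial_vorticity <- function(sample) {
  if (nrow(sample$w) < 3 || ncol(sample$w) < 3)
    abort("plane lattice must be at least 3 x 3.")
  h_m <- sample$spacing / 1000
  dv_dx <- masked_deriv(sample$v / 100, sample$lumen, h_m, dim = 1)
  du_dy <- masked_deriv(sample$u / 100, sample$lumen, h_m, dim = 2)
  dv_dx - du_dy
}

#' Wall-to-wall chord profile of velocity
#'
#' Samples the through-plane velocity `w` and the cross-flow velocity `u_c`
#' (in-plane component perpendicular to the chord) along the chord through
#' the lumen centroid, oriented so the normalised coordinate x/X = 0 lies on
#' the convex-side wall (positive `axis1` direction) and x/X = 1 on the
#' concave side.
#'
#' @param sample A [extract_plane()] result.
#' @param n_points Number of samples along the chord (>= 5).
#' @param direction Unit 2-vector (components along `axis1`, `axis2`) of the
#'   chord; default `c(1, 0)`, the convex-concave diameter.
#' @param wall_inset Distance in mm by which both chord endpoints are pulled
#'   inside the detected wall. The default 0 places the endpoints on the
#'   lumen boundary; wall-shear estimation on voxelised data benefits from a
#'   small inset (see [wall_shear_summary()]) because interpolation within
#'   one lattice cell of the wall mixes in exterior voxels.
#' @return A `chord_profile` tibble: `x_norm` (0 to 1), `s_mm` (physical
#'   coordinate from the convex wall), `w_cm_s`, `u_c_cm_s`; chord length in
#'   attribute `chord_length_mm`.
#' @export
chord_profile <- function(sample, n_points = 101, direction = c(1, 0),
                          wall_inset = 0) {
  direction <- direction / sqrt(sum(direction^2))
  lum <- sample$lumen
  if (!any(lum)) abort("chord misses the lumen: empty plane sample.")
  idx <- which(lum, arr.ind = TRUE)
  centroid <- c(mean(sample$coords1[idx[, 1]]), mean(sample$coords2[idx[, 2]]))
  res <- sample$spacing
  hw <- max(abs(c(sample$coords1, sample$coords2))) * sqrt(2)
  step <- res / 4
  tt <- seq(-hw, hw, by = step)
  pts_p <- centroid[1] + tt * direction[1]
  pts_q <- centroid[2] + tt * direction[2]
  pi_ <- (pts_p - sample$coords1[1]) / res + 1
  pj <- (pts_q - sample$coords2[1]) / res + 1
  on <- round(pi_) >= 1 & round(pi_) <= nrow(lum) &
        round(pj) >= 1 & round(pj) <= ncol(lum)
  inside <- rep(FALSE, length(tt))
  inside[on] <- lum[cbind(round(pi_[on]), round(pj[on]))]
  i0 <- which.min(abs(tt))
  if (!inside[i0]) abort("chord misses the lumen at the centroid.")
  lo <- i0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(tt) && inside[hi + 1]) hi <- hi + 1
  # wall estimate: the projection of the outermost inside lattice-cell
  # centre onto the chord. Cell centres are known exactly, whereas the
  # boolean indicator transition overshoots the wall by up to half a cell;
  # lumen cell centres always lie inside the lumen.
  cell_t <- function(i) {
    ctr <- c(sample$coords1[round(pi_[i])], sample$coords2[round(pj[i])])
    sum((ctr - centroid) * direction)
  }
  t_lo <- cell_t(lo) + wall_inset
  t_hi <- cell_t(hi) - wall_inset
  if (t_hi - t_lo < 2 * res) abort("degenerate chord: lumen thinner than two lattice cells.")
  # travel from the convex-side wall (positive axis1 projection) inward
  convexness <- direction[1]
  from <- if (convexness >= 0) t_hi else t_lo
  to <- if (convexness >= 0) t_lo else t_hi
  ts <- seq(from, to, length.out = n_points)
  cp <- centroid[1] + ts * direction[1]
  cq <- centroid[2] + ts * direction[2]
  ci <- (cp - sample$coords1[1]) / res + 1
  cj <- (cq - sample$coords2[1]) / res + 1
  w <- bilinear(sample$w, ci, cj)
  u <- bilinear(sample$u, ci, cj)
  v <- bilinear(sample$v, ci, cj)
  # cross-flow direction: normal x travel, expressed in plane coordinates
  travel <- sign(to - from) * direction
  cross_dir <- c(-travel[2], travel[1])
  u_c <- u * cross_dir[1] + v * cross_dir[2]
  w[is.na(w)] <- 0; u_c[is.na(u_c)] <- 0
  len <- abs(to - from)
  out <- tibble(x_norm = seq(0, 1, length.out = n_points),
                s_mm = seq(0, len, length.out = n_points),
                w_cm_s = w, u_c_cm_s = u_c)
  attr(out, "chord_length_mm") <- len
  attr(out, "frame") <- sample$frame
  class(out) <- c("chord_profile", class(out))
  out
}

#' Shear stress along a chord
#'
#' Adds the streamwise and cross-flow shear components
#' `tau_ax = mu * dw/ds` and `tau_tan = mu * du_c/ds` (chord-directional
#' derivatives; central differences in the interior, second-order one-sided
#' at the walls). The values at x/X = 0 and 1 are the axial and tangential
#' wall shear stress.
#'
#' @param chord A [chord_profile()] with >= 5 points.
#' @param constants A [physical_constants()] supplying the dynamic viscosity;
#'   all shear values scale linearly in it.
#' @return The chord tibble with columns `tau_ax_pa` and `tau_tan_pa` added.
#' @export
shear_profile <- function(chord, constants = physical_constants()) {
  if (nrow(chord) < 5) abort("chord must have at least 5 points.")
  len <- attr(chord, "chord_length_mm")
  if (is.null(len) || len <= 0) abort("degenerate chord length.")
  mu <- constants$dynamic_viscosity
  s_m <- chord$s_mm / 1000
  out <- mutate(chord,
                tau_ax_pa = mu * gradient_1d(chord$w_cm_s / 100, s_m),
                tau_tan_pa = mu * gradient_1d(chord$u_c_cm_s / 100, s_m))
  attributes(out)$chord_length_mm <- len
  attributes(out)$frame <- attr(chord, "frame")
  out
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |sum(tau dt)| / sum(|tau| dt))`: 0 for unidirectional
#' shear, 0.5 for fully oscillatory (zero-mean) shear; 0 when the shear is
#' identically zero. Uniform frame spacing is assumed, so the time step
#' cancels.
#'
#' @param tau Shear time series over one cycle: a numeric vector, or a matrix
#'   with time in rows (one OSI per column).
#' @return OSI in \[0, 0.5\].
#' @export
#' @examples
#' osi(c(1, 2, 1, 0.5))          # 0 (unidirectional)
#' osi(sin(2 * pi * (0:19) / 20))  # 0.5 (zero mean)
osi <- function(tau) {
  one <- function(x) {
    denom <- sum(abs(x))
    if (denom == 0) return(0)
    0.5 * (1 - abs(sum(x)) / denom)
  }
  if (is.matrix(tau)) apply(tau, 2, one) else one(tau)
}

#' Wall shear stress and OSI summary at the chord endpoints
#'
#' Evaluates the chord shear profile on every frame, reporting for each wall
#' (x/X = 0, convex; x/X = 1, concave) the axial and tangential wall shear
#' stress at peak systole (averaged over the peak frame and its two
#' neighbours for robustness to measurement noise) and the OSI of each
#' component over the cycle.
#'
#' @inheritParams plane_flux
#' @param constants A [physical_constants()].
#' @param n_points Samples per chord.
#' @param wall_inset Inset of the chord endpoints in mm; the default (one
#'   in-plane lattice cell) keeps the wall estimates clear of partial-volume
#'   smearing at the lumen boundary.
#' @param wall_window Length in mm of the near-wall segment over which the
#'   wall velocity gradient is fitted by least squares (default: two lattice
#'   cells). A short fitted segment is much less noise-sensitive than a
#'   single one-sided difference on interpolated voxel data.
#' @return A `wss_result` tibble with rows `convex` / `concave`: columns
#'   `side`, `x_norm`, `tau_ax_peak_pa`, `tau_tan_peak_pa`, `osi_ax`,
#'   `osi_tan`, plus attribute `peak_frame`. Peak values are means over the
#'   peak-systolic frame and its two neighbours on each side.
#' @export
wall_shear_summary <- function(field, mask, label, plane,
                               constants = physical_constants(),
                               n_points = 101, wall_inset = NULL,
                               wall_window = NULL) {
  n <- field$meta$n_frames
  mu <- constants$dynamic_viscosity
  # LS slope of velocity (cm/s) over the near-wall chord samples, in Pa
  wall_tau <- function(s_mm, v_cm_s, sel) {
    fit <- stats::lm.fit(cbind(1, s_mm[sel] / 1000), v_cm_s[sel] / 100)
    mu * unname(fit$coefficients[2])
  }
  tau <- purrr::map(seq_len(n), function(k) {
    smp <- extract_plane(field, mask, label, plane, k)
    inset <- wall_inset %||% smp$spacing
    win <- wall_window %||% (2 * smp$spacing)
    ch <- chord_profile(smp, n_points, wall_inset = inset)
    len <- attr(ch, "chord_length_mm")
    s0 <- which(ch$s_mm <= win)
    s1 <- which(ch$s_mm >= len - win)
    list(ax = c(wall_tau(ch$s_mm, ch$w_cm_s, s0),
                -wall_tau(ch$s_mm, ch$w_cm_s, s1)),
         tan = c(wall_tau(ch$s_mm, ch$u_c_cm_s, s0),
                 -wall_tau(ch$s_mm, ch$u_c_cm_s, s1)),
         mean_w = mean(abs(ch$w_cm_s)))
  })
  ax <- t(vapply(tau, `[[`, numeric(2), "ax"))    # frames x 2 walls
  tn <- t(vapply(tau, `[[`, numeric(2), "tan"))
  peak <- which.max(vapply(tau, `[[`, numeric(1), "mean_w"))
  around <- unique(pmin(pmax(peak + (-2:2), 1), n))
  out <- tibble(side = c("convex", "concave"), x_norm = c(0, 1),
                tau_ax_peak_pa = colMeans(ax[around, , drop = FALSE]),
                tau_tan_peak_pa = colMeans(tn[around, , drop = FALSE]),
                osi_ax = osi(ax), osi_tan = osi(tn))
  attr(out, "peak_frame") <- peak
  class(out) <- c("wss_result", class(out))
  out
}
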