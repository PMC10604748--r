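#' Idealised aortic-arch centreline geometry
#'
#' Builds a planar candy-cane centreline: a straight ascending limb (20 % of
#' the aortic length), a 180-degree arch (45 %), and a straight descending
#' limb (35 %), sampled at half the finest voxel spacing. The geometry lies
#' in the arch (x-z) plane, centred in the grid's field of view; torsion is
#' omitted since the analyses exercised (flux, transit-time PWV, vorticity,
#' chord shear) do not require it. Each centreline point carries its
#' arclength, unit tangent, and the unit vector toward the convex (outer
#' curvature) wall used to orient chord profiles.
#'
#' @param config A [phantom_config()].
#' @return An `aorta_geometry` list with matrix `centerline` (n x 3, mm),
#'   vector `arclength` (mm), matrices `tangent` and `convex_dir` (n x 3,
#'   unit rows), vector `radius` (mm) and the arch parameters.
#' @export
#' @examples
#' geo <- make_geometry(phantom_config("TAV"))
#' range(geo$arclength)
make_geometry <- function(config) {
  L <- config$aortic_length
  R <- config$lumen_radius
  if (L <= 4 * R)
    abort("`aortic_length` must exceed 4 * lumen_radius for a tube geometry.")
  meta <- config$grid$meta
  dims <- config$grid$dim
  extent <- (dims - 1) * meta$voxel_spacing

  f_asc <- 0.20; f_arc <- 0.45
  L_asc <- f_asc * L
  L_arc <- f_arc * L
  L_desc <- L - L_asc - L_arc
  Rc <- L_arc / pi  # arch radius of the 180-degree arc

  r_max <- R * sqrt(1 + config$area_pulsation)
  if (2 * Rc + 2 * r_max > extent[1] || 2 * r_max > extent[2])
    abort("lumen radius / arch too large for the grid extent.")
  if (Rc <= r_max)
    abort("lumen radius too large: arch inner curvature would self-intersect.")

  # arch centre, placed so the structure is centred in the field of view
  z_top <- L_asc + Rc + r_max
  z_bot <- min(0, L_asc - L_desc) - r_max
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  z0 <- (extent[3] - (z_top - z_bot)) / 2 - z_bot  # world z of centreline start
  Cz <- z0 + L_asc                                # arch centre height

  h <- min(meta$voxel_spacing) / 2
  s <- seq(0, L, by = h)
  if (s[length(s)] < L) s <- c(s, L)
  n <- length(s)
  P <- matrix(0, n, 3)
  Tg <- matrix(0, n, 3)
  asc <- s <= L_asc
  arc <- s > L_asc & s <= L_asc + L_arc
  dsc <- s > L_asc + L_arc
  # ascending limb: straight up at x = cx - Rc
  P[asc, ] <- cbind(cx - Rc, cy, z0 + s[asc])
  Tg[asc, ] <- matrix(c(0, 0, 1), sum(asc), 3, byrow = TRUE)
  # arch: semicircle over the top, angle runs from pi down to 0 in x-z
  th <- pi - (s[arc] - L_asc) / Rc
  P[arc, ] <- cbind(cx + Rc * cos(th), cy, Cz + Rc * sin(th))
  Tg[arc, ] <- cbind(sin(th), 0, -cos(th))
  # descending limb: straight down at x = cx + Rc
  P[dsc, ] <- cbind(cx + Rc, cy, Cz - (s[dsc] - L_asc - L_arc))
  Tg[dsc, ] <- matrix(c(0, 0, -1), sum(dsc), 3, byrow = TRUE)

  # convex direction: component of (P - arch centre) orthogonal to the tangent
  Cc <- c(cx, cy, Cz)
  rel <- sweep(P, 2, Cc, "-")
  proj <- rowSums(rel * Tg)
  conv <- rel - Tg * proj
  conv <- conv / sqrt(rowSums(conv^2))

  structure(list(centerline = P, arclength = s, tangent = Tg,
                 convex_dir = conv, radius = rep(R, n),
                 arch_center = Cc, arch_radius = Rc,
                 segment_lengths = c(ascending = L_asc, arch = L_arc,
                                     descending = L_desc),
                 aortic_length = L),
            class = "aorta_geometry")
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf("<aorta_geometry> length %.1f mm (asc %.1f + arch %.1f + desc %.1f), arch radius %.1f mm, %d points\n",
              x$aortic_length, x$segment_lengths[1], x$segment_lengths[2],
              x$segment_lengths[3], x$arch_radius, nrow(x$centerline)))
  invisible(x)
}

#' Oriented short-axis analysis plane
#'
#' @param origin Plane origin in world mm.
#' @param normal Unit plane normal (through-plane / axial direction).
#' @param axis1,axis2 In-plane orthonormal axes; `axis1 x axis2 = normal`.
#'   If omitted they are constructed from the normal.
#' @param radius In-plane sampling radius in mm: voxels farther than this
#'   from the origin are ignored, so a plane through a curved vessel samples
#'   only the local cross-section (default `Inf`).
#' @return An `analysis_plane` object.
#' @export
analysis_plane <- function(origin, normal, axis1 = NULL, axis2 = NULL,
                           radius = Inf) {
  normal <- unit3(normal)
  if (is.null(axis1)) {
    ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    axis1 <- unit3(cross3(ref, normal))
  } else axis1 <- unit3(axis1)
  if (is.null(axis2)) axis2 <- cross3(normal, axis1) else axis2 <- unit3(axis2)
  G <- rbind(normal, axis1, axis2)
  if (max(abs(G %*% t(G) - diag(3))) > 1e-9)
    abort("{normal, axis1, axis2} must be orthonormal (to 1e-9).")
  if (max(abs(cross3(axis1, axis2) - normal)) > 1e-9)
    abort("axes must be right-handed: axis1 x axis2 = normal.")
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius <= 0)
    abort("`radius` must be a single positive number (Inf allowed).")
  structure(list(origin = as.numeric(origin), normal = normal,
                 axis1 = axis1, axis2 = axis2, radius = radius),
            class = "analysis_plane")
}

#' @export
print.analysis_plane <- function(x, ...) {
  cat(sprintf("<analysis_plane> origin (%s) mm, normal (%s)\n",
              paste(signif(x$origin, 4), collapse = ", "),
              paste(signif(x$normal, 3), collapse = ", ")))
  invisible(x)
}

#' Analysis plane at an arclength fraction of the centreline
#'
#' The plane normal is the centreline tangent (so positive flux follows the
#' flow direction), `axis1` points toward the convex (outer-curvature) wall
#' — chord profiles start there (x/X = 0) — and `axis2 = normal x axis1`.
#'
#' @param geometry An [make_geometry()] result.
#' @param fraction Arclength fraction in \[0, 1\]; the anatomically motivated
#'   defaults used by the pipeline are 0.15 (ascending aorta, proximal to the
#'   sinotubular junction) and 0.85 (descending aorta).
#' @return An [analysis_plane()].
#' @export
plane_at <- function(geometry, fraction) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  i <- which.min(abs(geometry$arclength - fraction * geometry$aortic_length))
  # sampling radius below the arch radius keeps the plane from also cutting
  # the opposite limb of the candy-cane
  analysis_plane(origin = geometry$centerline[i, ],
                 normal = geometry$tangent[i, ],
                 axis1 = geometry$convex_dir[i, ],
                 radius = 0.95 * geometry$arch_radius)
}
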