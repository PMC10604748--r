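# Internal numerical helpers shared across modules.

# Trilinear interpolation of a 3-D array at continuous 1-based voxel indices.
# pts is an n x 3 matrix; points outside the grid return `fill`.
trilinear <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v <- vol[idx(x0,     y0,     z0    )] * (1 - fx) * (1 - fy) * (1 - fz) +
       vol[idx(x0 + 1, y0,     z0    )] * fx       * (1 - fy) * (1 - fz) +
       vol[idx(x0,     y0 + 1, z0    )] * (1 - fx) * fy       * (1 - fz) +
       vol[idx(x0 + 1, y0 + 1, z0    )] * fx       * fy       * (1 - fz) +
       vol[idx(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
       vol[idx(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
       vol[idx(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
       vol[idx(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  out[inside] <- v
  out
}

# Nearest-neighbour lookup of a 3-D array at continuous 1-based indices.
nearest_voxel <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(pts))
  out[inside] <- vol[cbind(i[inside], j[inside], k[inside])]
  out
}

# Gradient of y with respect to a (possibly non-uniform) coordinate s:
# central differences in the interior, 3-point one-sided at both ends.
gradient_1d <- function(y, s) {
  n <- length(y)
  if (n < 3) abort("gradient_1d() needs at least 3 samples.")
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  # second-order one-sided stencils (uniform-spacing form is exact here for
  # the uniform chords used throughout; falls back gracefully otherwise)
  h1 <- s[2] - s[1]
  g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h1)
  hn <- s[n] - s[n - 1]
  g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * hn)
  g
}

# Cross product of two length-3 vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("Cannot normalise a zero vector.")
  v / n
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
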