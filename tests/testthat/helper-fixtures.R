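# Shared fixtures: phantoms are expensive (~10 s each), so noise-free
# reference phantoms are generated once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(mode, noise_sd = 0, seed = 1L) {
  key <- paste(mode, noise_sd, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_phantom(
      phantom_config(mode, noise_sd = noise_sd, seed = seed))
  }
  .fixture_cache[[key]]
}

# Analytic plane sample on a square lattice: fu/fv/fw are functions of the
# in-plane coordinates (p, q) in mm returning cm/s; the lumen is the disc of
# radius R.
make_plane_sample <- function(fu, fv, fw, R = 10, res = 0.25, margin = 2) {
  g <- seq(-(R + margin), R + margin, by = res)
  gg <- expand.grid(p = g, q = g)
  shape <- function(x) matrix(x, length(g), length(g))
  out <- list(u = shape(fu(gg$p, gg$q)),
              v = shape(fv(gg$p, gg$q)),
              w = shape(fw(gg$p, gg$q)),
              lumen = shape(gg$p^2 + gg$q^2 <= R^2),
              coords1 = g, coords2 = g, spacing = res,
              plane = analysis_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
              frame = 1L)
  class(out) <- "plane_sample"
  out
}

# Small random label mask pair for Dice property tests.
random_masks <- function(seed, p = 0.3, dims = c(8, 8, 8)) {
  set.seed(seed)
  m <- grid_meta(c(1, 1, 1))
  a <- array(ifelse(stats::runif(prod(dims)) < p, 7L, 0L), dims)
  b <- array(ifelse(stats::runif(prod(dims)) < p, 7L, 0L), dims)
  list(pred = label_mask(a, m), truth = label_mask(b, m))
}

# Brute-force Dice oracle on voxel index sets.
dice_bruteforce <- function(a, b, label) {
  A <- which(a$labels == label)
  B <- which(b$labels == label)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# Helper: straight-tube velocity field + mask on a uniform grid for the
# flux/KE closed-form tests. Velocity vz is constant inside a 10x10 column.
straight_tube <- function(vz = 10, n_frames = 3, vx = 0, vy = 0) {
  dims <- c(14, 14, 8)
  meta <- grid_meta(c(1, 1, 1), n_frames, frame_interval = 50, venc = 200)
  arr <- array(0, dim = c(dims, n_frames, 3))
  lab <- array(0L, dims)
  lab[3:12, 3:12, ] <- 7L
  for (k in seq_len(n_frames)) {
    arr[3:12, 3:12, , k, 1] <- vx
    arr[3:12, 3:12, , k, 2] <- vy
    arr[3:12, 3:12, , k, 3] <- vz
  }
  list(field = velocity_field(arr, meta),
       mask = label_mask(lab, meta),
       plane = analysis_plane(c(6.5, 6.5, 4), c(0, 0, 1), c(1, 0, 0)))
}
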