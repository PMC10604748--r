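#' Acquisition grid metadata
#'
#' Describes the sampling lattice of a 4D phase-contrast MRI acquisition:
#' voxel spacing, number of cardiac phases, phase (frame) interval, velocity
#' encoding limit (venc) and the world-space position of the first voxel
#' centre. World coordinates are axis-aligned:
#' `world = origin + (index - 1) * spacing` (oblique affines are rejected at
#' the I/O layer).
#'
#' @param voxel_spacing Length-3 numeric, voxel spacing in mm (x, y, z).
#' @param n_frames Number of cardiac phases (>= 1).
#' @param frame_interval Time between phases in ms.
#' @param venc Velocity-encoding limit in cm/s; measured velocities beyond it
#'   alias and are clipped/flagged by the phantom generator.
#' @param origin Length-3 numeric, world position (mm) of voxel (1,1,1).
#' @return A `grid_meta` object (list).
#' @export
#' @examples
#' grid_meta(c(0.9, 0.9, 2.4), n_frames = 30, frame_interval = 857 / 30)
grid_meta <- function(voxel_spacing, n_frames = 1L, frame_interval = 1,
                      venc = 200, origin = c(0, 0, 0)) {
  if (length(voxel_spacing) != 3 || !all(is.finite(voxel_spacing)))
    abort("`voxel_spacing` must be three finite numbers (mm).")
  if (any(voxel_spacing <= 0))
    abort("`voxel_spacing` must be > 0 in every direction.")
  if (length(n_frames) != 1 || n_frames < 1 || n_frames != round(n_frames))
    abort("`n_frames` must be a single integer >= 1.")
  check_scalar(frame_interval, "frame_interval")
  check_scalar(venc, "venc")
  if (length(origin) != 3 || !all(is.finite(origin)))
    abort("`origin` must be three finite numbers (mm).")
  structure(list(voxel_spacing = as.numeric(voxel_spacing),
                 n_frames = as.integer(n_frames),
                 frame_interval = as.numeric(frame_interval),
                 venc = as.numeric(venc),
                 origin = as.numeric(origin)),
            class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("<grid_meta> spacing %s mm, %d frames @ %.2f ms, venc %g cm/s\n",
              paste(signif(x$voxel_spacing, 3), collapse = " x "),
              x$n_frames, x$frame_interval, x$venc))
  invisible(x)
}

#' Standard cardiovascular label vocabulary
#'
#' Label ids for the structures segmented in a whole-heart mask: left
#' ventricle (LV), myocardium, left atrium (LA), right ventricle (RV), right
#' atrium (RA), pulmonary artery (PA) and aorta, plus background 0.
#'
#' @return Named integer vector mapping structure name to label id.
#' @export
#' @examples
#' aorta_vocabulary()["aorta"]
aorta_vocabulary <- function() {
  c(background = 0L, LV = 1L, myocardium = 2L, LA = 3L,
    RV = 4L, RA = 5L, PA = 6L, aorta = 7L)
}

#' Time-resolved three-directional velocity field
#'
#' Container for the 4D-PCMRI measurement: one velocity vector (vx, vy, vz)
#' per voxel per cardiac phase, stored as a 5-D array
#' `[x, y, z, frame, component]` in cm/s (the native phase-contrast
#' convention; downstream physics converts to SI internally).
#'
#' @param values 5-D numeric array `[nx, ny, nz, n_frames, 3]`, cm/s.
#' @param meta A [grid_meta()] whose `n_frames` matches `dim(values)[4]`.
#' @return A `velocity_field` object.
#' @export
velocity_field <- function(values, meta) {
  if (!inherits(meta, "grid_meta")) abort("`meta` must be a grid_meta object.")
  d <- dim(values)
  if (length(d) != 5 || d[5] != 3)
    abort("expected 3 velocity components: `values` must be [nx, ny, nz, n_frames, 3].")
  if (d[4] != meta$n_frames)
    abort(sprintf("`values` has %d frames but meta declares %d.", d[4], meta$n_frames))
  if (anyNA(values) || !all(is.finite(values)))
    abort("velocity values must all be finite (non-finite voxels found).")
  structure(list(values = values, meta = meta), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d frames, 3 components\n",
              d[1], d[2], d[3], d[4]))
  print(x$meta)
  invisible(x)
}

#' Integer-labelled segmentation mask
#'
#' A 3-D lattice of integer structure labels sharing the spatial grid of a
#' velocity field, with a vocabulary mapping label ids to structure names.
#'
#' @param labels 3-D integer array of label ids (0 = background).
#' @param meta A [grid_meta()] (spatial part is used).
#' @param vocabulary Named integer vector, see [aorta_vocabulary()].
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, meta, vocabulary = aorta_vocabulary()) {
  if (!inherits(meta, "grid_meta")) abort("`meta` must be a grid_meta object.")
  if (length(dim(labels)) != 3) abort("`labels` must be a 3-D array.")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    abort("labels must be non-negative integers.")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, as.integer(vocabulary))
  if (length(unknown) > 0)
    abort(sprintf("mask contains label id(s) absent from the vocabulary: %s",
                  paste(unknown, collapse = ", ")))
  structure(list(labels = labels, meta = meta, vocabulary = vocabulary),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  present <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  nm <- names(x$vocabulary)[match(present, x$vocabulary)]
  cat(sprintf("<label_mask> %d x %d x %d voxels; structures: %s\n",
              d[1], d[2], d[3],
              if (length(nm)) paste(nm, collapse = ", ") else "(none)"))
  invisible(x)
}

# Resolve a structure label given either its id or its vocabulary name.
resolve_label <- function(mask, label) {
  if (is.character(label)) {
    if (!label %in% names(mask$vocabulary))
      abort(sprintf("unknown structure name '%s'.", label))
    return(as.integer(mask$vocabulary[[label]]))
  }
  as.integer(label)
}

# Check that a velocity field and mask share a spatial grid.
check_paired <- function(field, mask) {
  df <- dim(field$values)[1:3]
  dm <- dim(mask$labels)
  if (!all(df == dm))
    abort(sprintf("spatial shape mismatch: velocity %s vs mask %s.",
                  paste(df, collapse = "x"), paste(dm, collapse = "x")))
  invisible(TRUE)
}

# World coordinates (mm) of 1-based voxel indices (n x 3 matrix in, n x 3 out).
voxel_to_world <- function(idx, meta) {
  sweep(sweep(idx - 1, 2, meta$voxel_spacing, "*"), 2, meta$origin, "+")
}

# Continuous 1-based voxel indices of world coordinates (mm).
world_to_voxel <- function(pts, meta) {
  sweep(sweep(pts, 2, meta$origin, "-"), 2, meta$voxel_spacing, "/") + 1
}
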