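# NIfTI round-tripping for velocity fields and label masks.
#
# Canonical on-disk dialect: one 4-D NIfTI per velocity component
# (<prefix>_vx.nii.gz, _vy, _vz) plus a YAML sidecar (<prefix>_meta.yaml)
# carrying the acquisition metadata NIfTI has no standard slot for
# (venc, frame interval, origin, label vocabulary). A single 5-D file
# [x, y, z, t, component] is accepted on read. Only axis-aligned grids are
# supported; oblique orientation matrices are rejected.

component_suffixes <- c("_vx", "_vy", "_vz")

sidecar_path <- function(prefix) paste0(prefix, "_meta.yaml")

write_sidecar <- function(prefix, meta, vocabulary = NULL) {
  doc <- list(voxel_spacing_mm = as.numeric(meta$voxel_spacing),
              n_frames = meta$n_frames,
              frame_interval_ms = meta$frame_interval,
              venc_cm_s = meta$venc,
              origin_mm = as.numeric(meta$origin))
  if (!is.null(vocabulary))
    doc$vocabulary <- as.list(setNames(as.integer(vocabulary), names(vocabulary)))
  yaml::write_yaml(doc, sidecar_path(prefix))
}

read_sidecar <- function(prefix) {
  p <- sidecar_path(prefix)
  if (!file.exists(p)) return(NULL)
  yaml::read_yaml(p)
}

check_axis_aligned <- function(img, path) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error")) return(invisible(TRUE))
  rot <- abs(xf[1:3, 1:3])
  offdiag <- rot - diag(diag(rot))
  if (any(offdiag > 1e-4 * max(rot)))
    abort(sprintf("'%s' has an oblique orientation matrix; only axis-aligned grids are supported.", path))
  invisible(TRUE)
}

meta_from_header <- function(img, n_frames, path, sidecar = NULL,
                             meta_overrides = list()) {
  pd <- attr(img, "pixdim")
  spacing <- as.numeric(pd[1:3])
  frame_interval <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0)
    pd[4] * 1000 else NA_real_  # NIfTI time units here are seconds
  fields <- list(voxel_spacing = spacing,
                 n_frames = n_frames,
                 frame_interval = frame_interval,
                 venc = NA_real_,
                 origin = c(0, 0, 0))
  if (!is.null(sidecar)) {
    fields$voxel_spacing <- sidecar$voxel_spacing_mm %||% fields$voxel_spacing
    fields$frame_interval <- sidecar$frame_interval_ms %||% fields$frame_interval
    fields$venc <- sidecar$venc_cm_s %||% fields$venc
    fields$origin <- sidecar$origin_mm %||% fields$origin
  }
  for (nm in intersect(names(meta_overrides),
                       c("voxel_spacing", "frame_interval", "venc", "origin")))
    fields[[nm]] <- meta_overrides[[nm]]
  if (any(!is.finite(fields$voxel_spacing)) || any(fields$voxel_spacing <= 0))
    abort(sprintf("format error in '%s': voxel_spacing must be > 0 (got %s).",
                  path, paste(signif(fields$voxel_spacing, 4), collapse = ", ")))
  if (!is.finite(fields$frame_interval) || fields$frame_interval <= 0)
    abort(sprintf("format error in '%s': frame_interval missing or <= 0; supply it via the sidecar or `meta_overrides`.", path))
  if (!is.finite(fields$venc) || fields$venc <= 0)
    fields$venc <- 200  # venc is informational for analysis; default 2 m/s
  grid_meta(fields$voxel_spacing, fields$n_frames, fields$frame_interval,
            fields$venc, fields$origin)
}

#' Write a velocity field as NIfTI component volumes
#'
#' Writes one 4-D NIfTI per component (`<prefix>_vx.nii.gz` etc.) in double
#' precision plus a YAML metadata sidecar, so that
#' `read_velocity(write_velocity(f, p))` is value-identical.
#'
#' @param field A [velocity_field()].
#' @param prefix Output path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @seealso [read_velocity()]
#' @export
write_velocity <- function(field, prefix) {
  if (!inherits(field, "velocity_field")) abort("`field` must be a velocity_field.")
  meta <- field$meta
  for (c in 1:3) {
    img <- RNifti::asNifti(field$values[, , , , c, drop = TRUE])
    RNifti::pixdim(img) <- c(meta$voxel_spacing, meta$frame_interval / 1000)
    RNifti::writeNifti(img, paste0(prefix, component_suffixes[c], ".nii.gz"))
  }
  write_sidecar(prefix, meta)
  invisible(prefix)
}

#' Read a velocity field from NIfTI
#'
#' Accepts either the canonical per-component layout written by
#' [write_velocity()] (path prefix) or a single 5-D NIfTI file
#' `[x, y, z, t, component]`. Header metadata is populated from the NIfTI
#' header and the YAML sidecar when present, and can be overridden.
#'
#' @param path Path prefix of the component files, or a single `.nii`/`.nii.gz`
#'   file containing a 5-D array.
#' @param meta_overrides Named list overriding `voxel_spacing`,
#'   `frame_interval`, `venc` and/or `origin`.
#' @return A [velocity_field()].
#' @export
read_velocity <- function(path, meta_overrides = list()) {
  if (file.exists(path) && grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    check_axis_aligned(img, path)
    d <- dim(img)
    if (length(d) != 5 || d[5] != 3)
      abort(sprintf("expected 3 velocity components in '%s' (got dim [%s]).",
                    path, paste(d, collapse = ", ")))
    arr <- array(as.numeric(img), dim = d)
    prefix <- sub("\\.nii(\\.gz)?$", "", path)
    sidecar <- read_sidecar(prefix)
    meta <- meta_from_header(img, d[4], path, sidecar, meta_overrides)
  } else {
    files <- paste0(path, component_suffixes, ".nii.gz")
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
      abort(sprintf("expected 3 velocity components; missing file(s): %s",
                    paste(missing, collapse = ", ")))
    comps <- lapply(files, RNifti::readNifti)
    dims <- lapply(comps, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      abort("velocity component files disagree on array shape.")
    check_axis_aligned(comps[[1]], files[1])
    d <- dims[[1]]
    if (length(d) == 3) d <- c(d, 1L)  # single-frame acquisition
    sidecar <- read_sidecar(path)
    meta <- meta_from_header(comps[[1]], d[4], files[1], sidecar, meta_overrides)
    arr <- array(0, dim = c(d, 3))
    for (c in 1:3) arr[, , , , c] <- as.numeric(comps[[c]])
  }
  if (anyNA(arr) || !all(is.finite(arr)))
    abort(sprintf("format error in '%s': non-finite velocity voxels.", path))
  velocity_field(arr, meta)
}

#' Write a label mask as NIfTI
#'
#' @param mask A [label_mask()].
#' @param path Output file (`.nii` or `.nii.gz`); a YAML sidecar carrying the
#'   vocabulary and metadata is written next to it.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask")) abort("`mask` must be a label_mask.")
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- mask$meta$voxel_spacing
  RNifti::writeNifti(img, path)
  write_sidecar(sub("\\.nii(\\.gz)?$", "", path), mask$meta, mask$vocabulary)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @param path A `.nii`/`.nii.gz` file of integer labels.
#' @param vocabulary Named integer label vocabulary; defaults to the sidecar's
#'   vocabulary if present, else [aorta_vocabulary()]. Unknown label ids are
#'   an error listing the unmapped ids.
#' @param meta_overrides Named list overriding header metadata (see
#'   [read_velocity()]).
#' @return A [label_mask()].
#' @export
read_mask <- function(path, vocabulary = NULL, meta_overrides = list()) {
  if (!file.exists(path)) abort(sprintf("mask file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  check_axis_aligned(img, path)
  d <- dim(img)
  if (length(d) != 3) abort(sprintf("'%s' must be a 3-D label volume.", path))
  sidecar <- read_sidecar(sub("\\.nii(\\.gz)?$", "", path))
  if (is.null(vocabulary)) {
    vocabulary <- if (!is.null(sidecar$vocabulary))
      setNames(as.integer(unlist(sidecar$vocabulary)), names(sidecar$vocabulary))
    else aorta_vocabulary()
  }
  # masks are per-frame snapshots; a frame interval is not required of them
  defaults <- list(frame_interval = (sidecar$frame_interval_ms %||% 1))
  fields <- meta_from_header(img, 1L, path, sidecar,
                             modifyList(defaults, meta_overrides))
  labels <- array(as.integer(round(as.numeric(img))), dim = d)
  label_mask(labels, fields, vocabulary)
}
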