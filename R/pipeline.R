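# End-to-end orchestration: phantom generation or data ingestion through all
# analysis stages, with CSV/JSON reports and provenance capture.

#' Validate a pipeline run configuration
#'
#' A run configuration holds exactly one input source — `phantom` (a list of
#' [phantom_config()] arguments) or `input` (paths: `velocity` prefix/file
#' and a character vector `masks`, one per frame or a single mask) — plus
#' analysis settings: `planes` (arclength fractions `ascending`,
#' `descending`), `constants` (`blood_density`, `dynamic_viscosity`),
#' `aortic_length` (mm; required for real data, implied by the phantom) and
#' `seed`.
#'
#' @param config A list, or path to a YAML file.
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path.", class = "config_error")
  has_ph <- !is.null(config$phantom); has_in <- !is.null(config$input)
  if (has_ph == has_in)
    abort("exactly one of `phantom` or `input` must be present.", class = "config_error")
  config$planes <- modifyList(list(ascending = 0.15, descending = 0.85),
                              config$planes %||% list())
  if (any(unlist(config$planes) < 0 | unlist(config$planes) > 1))
    abort("plane arclength fractions must lie in [0, 1].", class = "config_error")
  cst <- config$constants %||% list()
  config$constants <- physical_constants(cst$blood_density %||% 1060,
                                         cst$dynamic_viscosity %||% 3.5e-3)
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("run_config", "list"))
}

load_pipeline_input <- function(config) {
  if (!is.null(config$phantom)) {
    args <- config$phantom
    args$seed <- args$seed %||% config$seed
    ph <- generate_phantom(do.call(phantom_config, args))
    list(velocity = ph$velocity, masks = ph$masks, geometry = ph$geometry,
         truth = ph$truth, aortic_length = ph$config$aortic_length)
  } else {
    inp <- config$input
    if (is.null(inp$velocity) || is.null(inp$masks))
      abort("`input` needs `velocity` and `masks` paths.", class = "config_error")
    vel <- read_velocity(inp$velocity)
    masks <- lapply(inp$masks, read_mask)
    if (length(masks) == 1) masks <- masks[[1]]
    if (is.null(config$aortic_length))
      abort("`aortic_length` (mm) is required for real data.", class = "config_error")
    list(velocity = vel, masks = masks, geometry = NULL, truth = NULL,
         aortic_length = config$aortic_length)
  }
}

# Planes for real data: without a centreline, axial (z-normal) planes at the
# configured fractions of the mask's aorta z-extent.
default_planes <- function(masks, fractions) {
  m <- mask_for_frame(masks, 1L)
  id <- resolve_label(m, "aorta")
  idx <- which(m$labels == id, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask contains no aorta voxels.", class = "data_error")
  zr <- range(idx[, 3])
  lapply(fractions, function(f) {
    z <- zr[1] + f * diff(zr)
    org <- voxel_to_world(matrix(c(mean(idx[, 1]), mean(idx[, 2]), z), 1), m$meta)
    analysis_plane(org, c(0, 0, 1), c(1, 0, 0))
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the dataset, computes flow curves at the ascending
#' and descending planes, cardiac metrics, arterial stiffness, kinetic
#' energy, short-axis vorticity and chord wall shear stress, and writes CSV
#' reports plus a provenance JSON to `out_dir`. Deterministic given the
#' seed.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of the in-memory results (`flow_summary`,
#'   `stiffness`, `wss`, `curves`, paths of the files written).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "stage_error", parent = e))
  }
  message("[aortaflow] loading input")
  dat <- stage("input", load_pipeline_input(config))

  message("[aortaflow] flow quantification")
  planes <- stage("planes", {
    if (!is.null(dat$geometry)) {
      list(asc = plane_at(dat$geometry, config$planes$ascending),
           desc = plane_at(dat$geometry, config$planes$descending))
    } else {
      pl <- default_planes(dat$masks, c(config$planes$ascending,
                                        config$planes$descending))
      list(asc = pl[[1]], desc = pl[[2]])
    }
  })
  curves <- stage("flow", list(
    asc = compute_flow_curve(dat$velocity, dat$masks, "aorta", planes$asc),
    desc = compute_flow_curve(dat$velocity, dat$masks, "aorta", planes$desc)))
  hr <- 60000 / curve_period(curves$asc)
  fm_asc <- flow_metrics(curves$asc, hr)
  fm_desc <- flow_metrics(curves$desc, hr)

  message("[aortaflow] arterial stiffness")
  areas <- stage("stiffness", area_curve(dat$masks, "aorta", planes$asc))
  plane_sep <- dat$aortic_length *
    (config$planes$descending - config$planes$ascending)
  stiff <- stage("stiffness",
                 assess_stiffness(curves$asc, curves$desc, areas, plane_sep,
                                  config$constants))

  message("[aortaflow] hemodynamic fields")
  peak <- which.max(curves$asc$flux_ml_s)
  vort <- stage("wss", {
    smp <- extract_plane(dat$velocity, dat$masks, "aorta", planes$asc, peak)
    om <- axial_vorticity(smp)
    ok <- is.finite(om)
    list(mean = mean(om[ok]), abs_ratio = abs(sum(om[ok])) / sum(abs(om[ok])))
  })
  wss <- stage("wss", wall_shear_summary(dat$velocity, dat$masks, "aorta",
                                         planes$asc, config$constants))
  chord <- stage("wss", shear_profile(
    chord_profile(extract_plane(dat$velocity, dat$masks, "aorta",
                                planes$asc, peak)), config$constants))
  ke <- stage("flow", kinetic_energy_curve(dat$velocity, dat$masks, "aorta",
                                           config$constants))

  flow_summary <- tibble(
    heart_rate_bpm = hr,
    net_volume_ml = fm_asc$net_volume_ml,
    ascending_flow_l_min = fm_asc$cardiac_output_l_min,
    descending_flow_l_min = fm_desc$cardiac_output_l_min,
    regurgitant_fraction_pct = fm_asc$regurgitant_fraction_pct,
    peak_ke_mj = max(ke$ke_mj),
    plane_mean_vorticity_s = vort$mean,
    vorticity_two_lobe = vort$abs_ratio < 0.1)

  files <- list(
    flow_curves = file.path(out_dir, "flow_curves.csv"),
    flow_summary = file.path(out_dir, "flow_summary.csv"),
    stiffness = file.path(out_dir, "stiffness.csv"),
    chord = file.path(out_dir, "chord_profile.csv"),
    wss = file.path(out_dir, "wss_summary.csv"),
    provenance = file.path(out_dir, "provenance.json"))
  curves_out <- bind_rows(
    mutate(as_tibble(curves$asc), plane = "ascending"),
    mutate(as_tibble(curves$desc), plane = "descending"))
  utils::write.csv(curves_out, files$flow_curves, row.names = FALSE)
  utils::write.csv(flow_summary, files$flow_summary, row.names = FALSE)
  utils::write.csv(tidy(stiff), files$stiffness, row.names = FALSE)
  utils::write.csv(as_tibble(chord), files$chord, row.names = FALSE)
  utils::write.csv(as_tibble(wss), files$wss, row.names = FALSE)
  prov <- list(package_version = as.character(utils::packageVersion("aortaflow")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = config$seed,
               config_hash = rlang::hash(unclass(config)),
               config = config[setdiff(names(config), "constants")])
  jsonlite::write_json(prov, files$provenance, auto_unbox = TRUE, digits = NA)

  invisible(list(flow_summary = flow_summary, stiffness = stiff, wss = wss,
                 curves = curves, areas = areas, kinetic_energy = ke,
                 vorticity = vort, files = files, truth = dat$truth))
}
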