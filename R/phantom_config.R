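#' Sampling grids for the synthetic phantom
#'
#' The full acquisition matrix follows the clinical 4D-PCMRI protocol
#' (320 x 320 x 100 voxels at 0.9 x 0.9 x 2.4 mm, 30 cardiac phases,
#' venc 2 m/s). The default `"reduced"` grid keeps the voxel spacing and
#' frame count but trims the field of view to 96 x 96 x 60 voxels, which
#' comfortably contains the phantom aorta and keeps a full double-precision
#' dataset around 0.4 GB instead of ~7 GB.
#'
#' @param size `"reduced"` (default) or `"full"`.
#' @param n_frames Cardiac phases per cycle.
#' @param frame_interval Phase interval in ms; defaults to `857 / n_frames`
#'   (the cycle at 70 bpm) and is overwritten by the phantom to match the
#'   configured heart rate.
#' @param venc Velocity-encoding limit in cm/s.
#' @return A list with `dim` (voxel counts) and a [grid_meta()].
#' @export
phantom_grid <- function(size = c("reduced", "full"), n_frames = 30,
                         frame_interval = 857 / n_frames, venc = 200) {
  size <- match.arg(size)
  dims <- switch(size, reduced = c(96L, 96L, 60L), full = c(320L, 320L, 100L))
  list(dim = dims,
       meta = grid_meta(c(0.9, 0.9, 2.4), n_frames, frame_interval, venc))
}

#' Configuration of the synthetic aorta flow phantom
#'
#' Defines a TAV- or BAV-like 4-D flow dataset: an idealised planar aortic
#' arch (ascending limb, 180-degree arch, descending limb) carrying a
#' systolic flow waveform with transit delay, wall-area pulsation, a valve
#' jet profile and mode-specific secondary flow, plus venc-clipped Gaussian
#' noise. Defaults are per-mode physiological values: TAV uses heart rate
#' 70 bpm, stroke volume 67 mL, regurgitant fraction 0.3 %, aortic length
#' 112 mm, PWV 3.9 m/s, area pulsation 0.30; BAV uses 47 bpm, 108 mL,
#' 1.5 %, 156 mm, 3.8 m/s, 0.27.
#'
#' @param valve_mode `"TAV"` (symmetric top-hat jet with a Dean vortex pair)
#'   or `"BAV"` (jet skewed toward the convex wall with a single
#'   counter-clockwise helical vortex).
#' @param heart_rate Heart rate in bpm.
#' @param stroke_volume Net ejected volume per beat in mL.
#' @param regurgitant_fraction Retrograde volume as % of forward volume.
#' @param aortic_length Centreline arclength in mm between the aortic root
#'   and the distal descending measurement region.
#' @param lumen_radius Lumen radius in mm (end-diastolic).
#' @param pwv Programmed pulse wave velocity in m/s (transit delay of the
#'   waveform along the centreline).
#' @param area_pulsation Relative systolic area increase \eqn{\Delta A / A}
#'   over the end-diastolic area.
#' @param swirl_ratio Peak in-plane (secondary-flow) speed as a fraction of
#'   the peak axial speed, in \[0, 1\].
#' @param boundary_layer_fraction Thickness of the near-wall linear ramp of
#'   the axial jet profile as a fraction of the lumen radius, in (0, 1).
#' @param noise_sd Additive Gaussian noise standard deviation per velocity
#'   component in cm/s.
#' @param seed Integer seed controlling the noise realisation.
#' @param grid A [phantom_grid()] (voxel counts + metadata).
#' @return A `phantom_config` list.
#' @export
#' @examples
#' phantom_config("TAV")
#' phantom_config("BAV", noise_sd = 0)
phantom_config <- function(valve_mode = c("TAV", "BAV"),
                           heart_rate = NULL,
                           stroke_volume = NULL,
                           regurgitant_fraction = NULL,
                           aortic_length = NULL,
                           lumen_radius = NULL,
                           pwv = NULL,
                           area_pulsation = NULL,
                           swirl_ratio = 0.4,
                           boundary_layer_fraction = 0.3,
                           noise_sd = 5,
                           seed = 1L,
                           grid = phantom_grid()) {
  valve_mode <- match.arg(valve_mode)
  defaults <- if (valve_mode == "TAV") {
    list(heart_rate = 70, stroke_volume = 67, regurgitant_fraction = 0.3,
         aortic_length = 112, lumen_radius = 10, pwv = 3.9,
         area_pulsation = 0.30)
  } else {
    list(heart_rate = 47, stroke_volume = 108, regurgitant_fraction = 1.5,
         aortic_length = 156, lumen_radius = 11, pwv = 3.8,
         area_pulsation = 0.27)
  }
  cfg <- list(valve_mode = valve_mode,
              heart_rate = heart_rate %||% defaults$heart_rate,
              stroke_volume = stroke_volume %||% defaults$stroke_volume,
              regurgitant_fraction = regurgitant_fraction %||% defaults$regurgitant_fraction,
              aortic_length = aortic_length %||% defaults$aortic_length,
              lumen_radius = lumen_radius %||% defaults$lumen_radius,
              pwv = pwv %||% defaults$pwv,
              area_pulsation = area_pulsation %||% defaults$area_pulsation,
              swirl_ratio = swirl_ratio,
              boundary_layer_fraction = boundary_layer_fraction,
              noise_sd = noise_sd,
              seed = as.integer(seed),
              grid = grid)
  check_scalar(cfg$heart_rate, "heart_rate")
  check_scalar(cfg$stroke_volume, "stroke_volume")
  if (cfg$regurgitant_fraction < 0 || cfg$regurgitant_fraction >= 100)
    abort("`regurgitant_fraction` must be in [0, 100).")
  check_scalar(cfg$aortic_length, "aortic_length")
  check_scalar(cfg$lumen_radius, "lumen_radius")
  check_scalar(cfg$pwv, "pwv")
  if (cfg$area_pulsation < 0) abort("`area_pulsation` must be >= 0.")
  if (cfg$swirl_ratio < 0 || cfg$swirl_ratio > 1)
    abort("`swirl_ratio` must be in [0, 1].")
  if (cfg$boundary_layer_fraction <= 0 || cfg$boundary_layer_fraction >= 1)
    abort("`boundary_layer_fraction` must be in (0, 1).")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  # grid frame interval follows the configured heart rate
  period <- 60000 / cfg$heart_rate
  cfg$grid$meta$frame_interval <- period / cfg$grid$meta$n_frames
  structure(cfg, class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %s: HR %g bpm, SV %g mL, rf %g%%, L %g mm, R %g mm, PWV %g m/s, dA/A %g\n",
    x$valve_mode, x$heart_rate, x$stroke_volume, x$regurgitant_fraction,
    x$aortic_length, x$lumen_radius, x$pwv, x$area_pulsation))
  cat(sprintf("  grid %s @ (%s) mm, %d frames; swirl %g, noise %g cm/s, seed %d\n",
              paste(x$grid$dim, collapse = "x"),
              paste(x$grid$meta$voxel_spacing, collapse = ", "),
              x$grid$meta$n_frames, x$swirl_ratio, x$noise_sd, x$seed))
  invisible(x)
}

#' Synthetic per-frame flux waveform
#'
#' One half-sine systolic lobe lasting one third of the cycle, followed by a
#' small negative early-diastolic lobe (one tenth of the cycle), zero flux
#' elsewhere. The sampled lobes are rescaled on the discrete frame grid so
#' that the periodic trapezoidal integrals are exact: forward volume equals
#' `stroke_volume / (1 - rf/100)` and net volume equals `stroke_volume`.
#'
#' @param heart_rate Heart rate in bpm.
#' @param stroke_volume Net volume per beat in mL (> 0).
#' @param regurgitant_fraction Backward/forward volume ratio in percent.
#' @param n_frames Number of frames per cycle (>= 10).
#' @return A [flow_curve()] of per-frame flux in mL/s.
#' @export
#' @examples
#' wf <- make_waveform(70, 67, 0.3, 30)
#' net_volume(wf)            # 67 mL by construction
#' regurgitant_fraction(wf)  # 0.3 %
make_waveform <- function(heart_rate, stroke_volume, regurgitant_fraction = 0,
                          n_frames = 30) {
  spec <- waveform_spec(heart_rate, stroke_volume, regurgitant_fraction, n_frames)
  t <- (seq_len(n_frames) - 1) * spec$period / n_frames
  flow_curve(t, waveform_fun(spec)(t), period_ms = spec$period)
}

# Continuous-time description of the programmed waveform. The two lobe
# amplitudes are normalised on the discrete frame grid, so the periodic
# trapezoidal volumes of the frame-sampled curve are exact: forward =
# SV / (1 - rf/100) and net = SV.
waveform_spec <- function(heart_rate, stroke_volume, regurgitant_fraction = 0,
                          n_frames = 30) {
  check_scalar(heart_rate, "heart_rate")
  if (!is.numeric(stroke_volume) || stroke_volume <= 0)
    abort("`stroke_volume` must be > 0.")
  if (regurgitant_fraction < 0 || regurgitant_fraction >= 100)
    abort("`regurgitant_fraction` must be in [0, 100).")
  if (n_frames < 10) abort("`n_frames` must be >= 10.")
  period <- 60000 / heart_rate
  dt <- period / n_frames
  t <- (seq_len(n_frames) - 1) * dt
  spec <- list(period = period, t_onset = 0.05 * period,
               tau_sys = period / 3, tau_dia = period / 10,
               amp_pos = 1, amp_neg = 1)
  shape_p <- waveform_lobes(t, spec)$pos
  shape_n <- waveform_lobes(t, spec)$neg
  fwd_target <- stroke_volume / (1 - regurgitant_fraction / 100)  # mL
  bwd_target <- fwd_target * regurgitant_fraction / 100
  dts <- dt / 1000
  spec$amp_pos <- fwd_target / (sum(shape_p) * dts)
  if (bwd_target > 0) {
    if (sum(shape_n) == 0) abort("frame grid too coarse to place the regurgitant lobe.")
    spec$amp_neg <- bwd_target / (sum(shape_n) * dts)
  } else spec$amp_neg <- 0
  spec
}

waveform_lobes <- function(t, spec) {
  tt <- t %% spec$period
  pos <- ifelse(tt >= spec$t_onset & tt <= spec$t_onset + spec$tau_sys,
                sin(pi * (tt - spec$t_onset) / spec$tau_sys), 0)
  t1 <- spec$t_onset + spec$tau_sys
  neg <- ifelse(tt > t1 & tt <= t1 + spec$tau_dia,
                sin(pi * (tt - t1) / spec$tau_dia), 0)
  list(pos = pos, neg = neg)
}

# Closure evaluating the continuous programmed waveform (mL/s) at any time.
waveform_fun <- function(spec) {
  function(t) {
    lb <- waveform_lobes(t, spec)
    spec$amp_pos * lb$pos - spec$amp_neg * lb$neg
  }
}
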