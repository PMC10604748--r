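#' Construct a flow curve
#'
#' A flow curve is the volumetric flux through an analysis plane over one
#' cardiac cycle: a tibble with columns `time_ms`, `flux_ml_s` and the
#' normalised time `t_norm` = t/T, carrying the cycle length as an attribute.
#' Frames are assumed uniformly spaced over the cycle; time integration
#' closes the cycle periodically (last frame wraps to the first).
#'
#' @param time_ms Strictly increasing frame times in ms.
#' @param flux_ml_s Flux samples in mL/s.
#' @param period_ms Cardiac cycle length in ms; defaults to
#'   `n * diff(time_ms)[1]` (uniform sampling).
#' @return A `flow_curve` tibble.
#' @export
#' @examples
#' flow_curve(seq(0, 950, by = 50), c(rep(0, 5), 200, 400, 200, rep(0, 12)))
flow_curve <- function(time_ms, flux_ml_s, period_ms = NULL) {
  if (length(time_ms) != length(flux_ml_s))
    abort("`time_ms` and `flux_ml_s` must have equal length.")
  if (length(time_ms) < 2 || any(diff(time_ms) <= 0))
    abort("`time_ms` must be strictly increasing with >= 2 samples.")
  if (is.null(period_ms)) period_ms <- length(time_ms) * diff(time_ms)[1]
  check_scalar(period_ms, "period_ms")
  out <- tibble(time_ms = as.numeric(time_ms),
                flux_ml_s = as.numeric(flux_ml_s),
                t_norm = as.numeric(time_ms) / period_ms)
  attr(out, "period_ms") <- period_ms
  class(out) <- c("flow_curve", class(out))
  out
}

curve_period <- function(curve) {
  p <- attr(curve, "period_ms")
  if (is.null(p)) p <- nrow(curve) * diff(curve$time_ms)[1]
  p
}

#' Net, forward and backward volumes of a flow curve
#'
#' Volumes are trapezoidal time integrals with the cycle closed periodically;
#' on a uniform frame grid this equals the Riemann sum
#' `sum(flux) * frame_interval`. Forward/backward split the positive and
#' negative flux lobes.
#'
#' @param curve A [flow_curve()] spanning one cardiac cycle.
#' @return `net_volume()`, `forward_volume()`, `backward_volume()`: volume in
#'   mL (backward is reported as a positive magnitude).
#' @export
net_volume <- function(curve) {
  dt <- curve_period(curve) / nrow(curve) / 1000  # s
  sum(curve$flux_ml_s) * dt
}

#' @rdname net_volume
#' @export
forward_volume <- function(curve) {
  dt <- curve_period(curve) / nrow(curve) / 1000
  sum(pmax(curve$flux_ml_s, 0)) * dt
}

#' @rdname net_volume
#' @export
backward_volume <- function(curve) {
  dt <- curve_period(curve) / nrow(curve) / 1000
  -sum(pmin(curve$flux_ml_s, 0)) * dt
}

#' Regurgitant fraction of a flow curve
#'
#' Retrograde volume as a percentage of forward volume through the plane per
#' cycle: `100 * backward / forward`.
#'
#' @param curve A [flow_curve()].
#' @return Regurgitant fraction in percent.
#' @export
#' @examples
#' t <- seq(0, 930, by = 31)
#' regurgitant_fraction(flow_curve(t, pmax(sin(2 * pi * t / 960), 0)))
regurgitant_fraction <- function(curve) {
  fwd <- forward_volume(curve)
  if (fwd <= 0) abort("forward volume is zero; regurgitant fraction undefined.")
  100 * backward_volume(curve) / fwd
}

#' Cardiac output from net volume and heart rate
#'
#' @param net_volume_ml Net ejected volume per beat in mL.
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @return Cardiac output in L/min.
#' @export
#' @examples
#' cardiac_output(67, 70)   # 4.69 L/min
#' cardiac_output(108, 47)  # 5.08 L/min
cardiac_output <- function(net_volume_ml, heart_rate_bpm) {
  check_scalar(net_volume_ml, "net_volume_ml")
  check_scalar(heart_rate_bpm, "heart_rate_bpm")
  net_volume_ml * heart_rate_bpm / 1000
}

#' One-row summary of a flow curve
#'
#' @param curve A [flow_curve()].
#' @param heart_rate_bpm Optional heart rate; if omitted it is inferred from
#'   the cycle length.
#' @return A tibble with net/forward/backward volume (mL), regurgitant
#'   fraction (%), peak flux (mL/s), heart rate (bpm) and cardiac output
#'   (L/min).
#' @export
flow_metrics <- function(curve, heart_rate_bpm = NULL) {
  period <- curve_period(curve)
  hr <- heart_rate_bpm %||% (60000 / period)
  nv <- net_volume(curve)
  tibble(heart_rate_bpm = hr,
         net_volume_ml = nv,
         forward_volume_ml = forward_volume(curve),
         backward_volume_ml = backward_volume(curve),
         regurgitant_fraction_pct = regurgitant_fraction(curve),
         peak_flux_ml_s = max(curve$flux_ml_s),
         cardiac_output_l_min = cardiac_output(nv, hr))
}
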