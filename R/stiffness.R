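# Transit-time pulse wave velocity, Bramwell-Hill distensibility, area
# pulsation and pressure drop.

#' Foot of a flow curve by the tangent method
#'
#' The systolic foot is the time where the tangent to the systolic upslope
#' intersects the pre-systolic baseline (the mean of the lowest quartile of
#' samples). At typical 4D-PCMRI temporal resolution (~30 ms per phase) the
#' slope at a single sample is dominated by sampling-phase quantisation, so
#' the tangent is fitted by least squares to the mid-upslope of the curve:
#' the periodic-spline upsampled samples between 25 % and 90 % of the
#' baseline-to-peak amplitude (the peak refined by a local parabola fit).
#' On a linear upslope this reduces exactly to the tangent through the ramp.
#'
#' @param curve A [flow_curve()] with a positive systolic upslope.
#' @param band Amplitude band (fractions of baseline-to-peak) over which the
#'   tangent is fitted.
#' @param resolution_ms Fine-grid step of the upsampled curve (ms).
#' @return Foot time in ms (same clock as `curve$time_ms`).
#' @export
#' @examples
#' t <- seq(0, 870, by = 30)
#' q <- pmax(sin(pi * (t - 120) / 290), 0) * 300
#' foot_time(flow_curve(t, q))  # close to the 120 ms onset
foot_time <- function(curve, band = c(0.25, 0.9), resolution_ms = 0.1) {
  t <- curve$time_ms
  q <- curve$flux_ml_s
  n <- length(q)
  period <- curve_period(curve)
  baseline <- mean(sort(q)[seq_len(max(1, floor(n / 4)))])
  ip <- which.max(q)
  if (q[ip] <= baseline) abort("no systolic upslope in the flow curve.")
  # refine the peak by a parabola through the three samples around the max
  y3 <- q[c(((ip - 2) %% n) + 1, ip, (ip %% n) + 1)]
  den <- 2 * y3[2] - y3[1] - y3[3]
  pk <- if (den > 0) y3[2] + (y3[3] - y3[1])^2 / (8 * den) else y3[2]
  if (!is.finite(pk) || pk < y3[2] || pk > y3[2] + (y3[2] - baseline)) pk <- y3[2]
  f <- stats::splinefun(c(t, t[1] + period), c(q, q[1]), method = "periodic")
  tf <- seq(t[ip] - period / 2, t[ip], by = resolution_ms)
  qf <- f(tf %% period)
  rel <- (qf - baseline) / (pk - baseline)
  below1 <- which(rel < band[1])
  below2 <- which(rel < band[2])
  if (length(below1) == 0 || length(below2) == 0)
    abort("no systolic upslope in the flow curve.")
  sel <- max(below1):max(below2)
  if (length(sel) < 2) abort("no systolic upslope in the flow curve.")
  fit <- stats::lm.fit(cbind(1, tf[sel]), qf[sel])
  m <- fit$coefficients[2]
  if (!is.finite(m) || m <= 0) abort("no systolic upslope in the flow curve.")
  unname((baseline - fit$coefficients[1]) / m)
}

#' Transit-time pulse wave velocity
#'
#' `PWV = L / dt` with the aortic length between the two analysis planes and
#' the transit time between the feet of the ascending and descending flow
#' curves.
#'
#' @param length_mm Centreline distance between the two planes in mm.
#' @param foot_asc_ms,foot_desc_ms Foot times (ms) of the ascending and
#'   descending flow curves; `foot_desc_ms` must exceed `foot_asc_ms`.
#' @return PWV in m/s.
#' @export
#' @examples
#' transit_pwv(112, 100, 135)  # 3.2 m/s
transit_pwv <- function(length_mm, foot_asc_ms, foot_desc_ms) {
  check_scalar(length_mm, "length_mm")
  dt <- foot_desc_ms - foot_asc_ms
  if (!is.finite(dt) || dt <= 0)
    abort("transit time must be positive (foot_desc_ms > foot_asc_ms).")
  (length_mm / 1000) / (dt / 1000)
}

#' Bramwell-Hill distensibility from pulse wave velocity
#'
#' `D = 1 / (rho * PWV^2)` in Pa^-1, reported per mmHg. The inverse
#' relation is [pwv_from_distensibility()].
#'
#' @param pwv Pulse wave velocity in m/s.
#' @param blood_density Blood density in kg/m^3.
#' @return Distensibility in 1/mmHg.
#' @export
#' @examples
#' distensibility_from_pwv(3.9)  # ~0.008 /mmHg
#' distensibility_from_pwv(3.8)  # ~0.009 /mmHg
distensibility_from_pwv <- function(pwv, blood_density = 1060) {
  if (any(pwv <= 0)) abort("`pwv` must be > 0.")
  133.322 / (blood_density * pwv^2)
}

#' @rdname distensibility_from_pwv
#' @param distensibility Distensibility in 1/mmHg.
#' @export
pwv_from_distensibility <- function(distensibility, blood_density = 1060) {
  if (any(distensibility <= 0)) abort("`distensibility` must be > 0.")
  1 / sqrt(blood_density * distensibility / 133.322)
}

#' Relative systolic area change of the ascending aorta
#'
#' `(A_peak_systole - A_end_diastole) / A_end_diastole`, with the two frames
#' located from the flow curve: peak systole at maximum flux, end diastole at
#' the last frame before the systolic foot.
#'
#' @param areas Per-frame cross-sectional areas (cm^2), e.g. from
#'   [area_curve()]; a numeric vector or a tibble with column `area_cm2`.
#' @param curve The ascending [flow_curve()] on the same frame grid.
#' @return Dimensionless \eqn{\Delta A / A}.
#' @export
delta_area_ratio <- function(areas, curve) {
  a <- if (is.data.frame(areas)) areas$area_cm2 else as.numeric(areas)
  if (length(a) != nrow(curve))
    abort("`areas` must have one value per frame of `curve`.")
  if (length(a) < 2) abort("need at least 2 frames.")
  i_peak <- which.max(curve$flux_ml_s)
  foot <- foot_time(curve)
  before <- which(curve$time_ms < foot)
  i_dia <- if (length(before) > 0) max(before) else length(a)
  (a[i_peak] - a[i_dia]) / a[i_dia]
}

#' Pressure drop from area pulsation and distensibility
#'
#' `dP = (dA/A) / D`, in mmHg.
#'
#' @param delta_area_ratio Dimensionless systolic area change.
#' @param distensibility Distensibility in 1/mmHg.
#' @return Pressure drop in mmHg.
#' @export
#' @examples
#' pressure_drop(0.3, 0.008)   # 37.5 mmHg
#' pressure_drop(0.27, 0.009)  # 30 mmHg
pressure_drop <- function(delta_area_ratio, distensibility) {
  if (any(distensibility <= 0)) abort("`distensibility` must be > 0.")
  delta_area_ratio / distensibility
}

#' Arterial stiffness assessment from two flow curves
#'
#' Combines the transit-time PWV (tangent time-to-foot method), Bramwell-Hill
#' distensibility, ascending area pulsation and the derived pressure drop
#' into one fitted-object-style result with [generics::tidy()] and
#' [generics::glance()] methods.
#'
#' @param asc_curve,desc_curve Ascending and descending [flow_curve()]s.
#' @param areas Per-frame ascending areas (cm^2), see [delta_area_ratio()].
#' @param length_mm Centreline distance between the two planes in mm.
#' @param constants A [physical_constants()].
#' @return A `stiffness_fit` object.
#' @export
assess_stiffness <- function(asc_curve, desc_curve, areas, length_mm,
                             constants = physical_constants()) {
  foot_asc <- foot_time(asc_curve)
  foot_desc <- foot_time(desc_curve)
  pwv <- transit_pwv(length_mm, foot_asc, foot_desc)
  D <- distensibility_from_pwv(pwv, constants$blood_density)
  daa <- delta_area_ratio(areas, asc_curve)
  structure(list(foot_asc_ms = foot_asc, foot_desc_ms = foot_desc,
                 transit_time_ms = foot_desc - foot_asc,
                 length_mm = length_mm, pwv_m_s = pwv,
                 distensibility_mmhg = D, delta_area_ratio = daa,
                 pressure_drop_mmhg = pressure_drop(daa, D),
                 blood_density = constants$blood_density),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<stiffness_fit> PWV %.2f m/s (L %.0f mm, transit %.1f ms), ",
           "D %.4f /mmHg, dA/A %.3f, dP %.1f mmHg\n"),
    x$pwv_m_s, x$length_mm, x$transit_time_ms, x$distensibility_mmhg,
    x$delta_area_ratio, x$pressure_drop_mmhg))
  invisible(x)
}
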