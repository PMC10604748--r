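#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stiffness assessment
#'
#' @param x A `stiffness_fit` from [assess_stiffness()].
#' @param ... Unused.
#' @return A tibble with one row per derived quantity (`term`, `estimate`,
#'   `unit`).
#' @export
tidy.stiffness_fit <- function(x, ...) {
  tibble(term = c("foot_asc", "foot_desc", "transit_time", "aortic_length",
                  "pwv", "distensibility", "delta_area_ratio", "pressure_drop"),
         estimate = c(x$foot_asc_ms, x$foot_desc_ms, x$transit_time_ms,
                      x$length_mm, x$pwv_m_s, x$distensibility_mmhg,
                      x$delta_area_ratio, x$pressure_drop_mmhg),
         unit = c("ms", "ms", "ms", "mm", "m/s", "1/mmHg", "", "mmHg"))
}

#' @rdname tidy.stiffness_fit
#' @return `glance()`: a one-row tibble of the headline quantities.
#' @export
glance.stiffness_fit <- function(x, ...) {
  tibble(pwv_m_s = x$pwv_m_s,
         distensibility_mmhg = x$distensibility_mmhg,
         delta_area_ratio = x$delta_area_ratio,
         pressure_drop_mmhg = x$pressure_drop_mmhg,
         transit_time_ms = x$transit_time_ms,
         aortic_length_mm = x$length_mm)
}

#' Tidy a phantom ground truth
#'
#' @param x A `phantom_truth` from [generate_phantom()].
#' @param ... Unused.
#' @return One row per programmed physiological parameter.
#' @export
tidy.phantom_truth <- function(x, ...) {
  tibble(term = c("heart_rate", "stroke_volume", "regurgitant_fraction",
                  "aortic_length", "pwv", "area_pulsation", "cardiac_output"),
         value = c(x$heart_rate, x$stroke_volume, x$regurgitant_fraction,
                   x$aortic_length, x$pwv, x$area_pulsation, x$cardiac_output),
         unit = c("bpm", "mL", "%", "mm", "m/s", "", "L/min"))
}
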