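# ggplot2 helpers for the standard result types (2-D analogues of the usual
# 4D-flow figures; no 3-D streamline rendering).

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   labs scale_fill_gradient2 coord_equal facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a flow curve
#'
#' @param object A [flow_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$t_norm, y = .data$flux_ml_s)) +
    geom_line() +
    labs(x = "t / T", y = "Flux (mL/s)") +
    theme_minimal()
}

#' Plot velocity and shear chord profiles
#'
#' @param object A [chord_profile()] (after [shear_profile()] the shear
#'   panels are included).
#' @param ... Unused.
#' @return A ggplot faceted by component.
#' @export
autoplot.chord_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::any_of(c("w_cm_s", "u_c_cm_s",
                                              "tau_ax_pa", "tau_tan_pa")),
                              names_to = "component", values_to = "value")
  ggplot(long, aes(x = .data$x_norm, y = .data$value)) +
    geom_line() +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "x / X (0 = convex wall)", y = NULL) +
    theme_minimal()
}

#' Short-axis view of a plane sample
#'
#' @param sample A [extract_plane()] result.
#' @param what `"speed"` (in-plane + through-plane magnitude, cm/s) or
#'   `"vorticity"` (axial vorticity, 1/s).
#' @return A ggplot raster of the lumen.
#' @export
plot_plane <- function(sample, what = c("speed", "vorticity")) {
  what <- match.arg(what)
  z <- switch(what,
              speed = sqrt(sample$u^2 + sample$v^2 + sample$w^2),
              vorticity = axial_vorticity(sample))
  z[!sample$lumen] <- NA
  df <- expand.grid(p = sample$coords1, q = sample$coords2)
  df$value <- as.vector(z)
  gg <- ggplot(df, aes(x = .data$p, y = .data$q, fill = .data$value)) +
    geom_raster() +
    coord_equal() +
    labs(x = "convex axis (mm)", y = "binormal axis (mm)",
         fill = if (what == "speed") "cm/s" else "1/s") +
    theme_minimal()
  if (what == "vorticity")
    gg <- gg + scale_fill_gradient2(low = "blue", mid = "white", high = "red")
  gg
}

#' @importFrom rlang .data
NULL
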