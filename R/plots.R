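#' Plot the scaling points and fitted saturating law
#'
#' Replicate-mean tissue uptake against nominal exchange area, with the
#' fitted rectangular hyperbola and the extrapolation target marked.
#'
#' @param object A `saturating_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturating_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    area_cm2 = seq(0, max(object$target_area, max(d$area_cm2)) * 1.05,
                   length.out = 200))
  curve$W <- predict(object, curve$area_cm2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area_cm2, y = .data$W_mean)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$W),
                       colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$W_mean - sqrt(.data$W_var),
      ymax = .data$W_mean + sqrt(.data$W_var))) +
    ggplot2::geom_vline(xintercept = object$target_area, linetype = "dashed") +
    ggplot2::labs(x = expression("exchange area A" ~ (cm^2)),
                  y = expression("steady-state tissue amount W" ~ (mu * M %.% cm^3)),
                  title = sprintf("W(A) = cA/(d+A): c = %.3g, d = %.3g, W* = %.3g",
                                  object$sat_level, object$half_area,
                                  object$W_star))
}

#' Plot per-level perfusion against mean radius with the extrapolation
#'
#' Log-log perfusion versus mean vessel radius, the fitted power law, and
#' the extrapolated value at the capillary-scale target radius.
#'
#' @param extrapolation Output of [extrapolate_flow()].
#' @return A ggplot.
#' @export
plot_flow_extrapolation <- function(extrapolation) {
  d <- extrapolation$data
  r_um <- d$mean_radius_cm * 1e4
  line <- tibble::tibble(
    r_um = exp(seq(log(extrapolation$target_radius_um * 0.8),
                   log(max(r_um) * 1.2), length.out = 100)))
  line$Q <- exp(extrapolation$log_intercept +
                  extrapolation$exponent * log(line$r_um * 1e-4))
  ggplot2::ggplot(d, ggplot2::aes(x = r_um, y = .data$flow_mL_min)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$Q), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = extrapolation$target_radius_um,
                      y = extrapolation$flow_mL_min, shape = 4, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression("mean vessel radius" ~ (mu * m)),
                  y = expression("total flow rate" ~ (mL ~ min^-1)))
}

#' Plot an axial tissue drug profile
#'
#' @param profile Output of [slice_profile()].
#' @return A ggplot.
#' @export
plot_slice_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mid, y = .data$W)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance along flow axis (cm)",
                  y = expression("tissue drug amount per slab" ~ (mu * M %.% cm^3)))
}
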